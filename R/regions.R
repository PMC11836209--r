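#' Tile a genome into fixed, non-overlapping windows
#'
#' Windows `[k*size + 1, (k+1)*size]` in 1-based closed coordinates,
#' anchored at position 1 on every chromosome and covering the mapped span;
#' each SNP maps to exactly one window (`window_of()`).
#'
#' @param loci Locus map (sorted).
#' @param window_size Window width in bp (default 500 kb).
#' @return Data frame: `chrom`, `window` (1-based index), `start`, `end`.
#' @export
tile_windows <- function(loci, window_size = 5e5) {
  check_loci(loci)
  out <- lapply(unique(loci$chrom), function(ch) {
    maxpos <- max(loci$pos[loci$chrom == ch])
    k <- seq_len(ceiling(maxpos / window_size))
    data.frame(chrom = ch, window = k,
               start = (k - 1) * window_size + 1,
               end = k * window_size, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname tile_windows
#' @param pos Positions in bp.
#' @return `window_of()`: the 1-based window index of each position.
#' @export
window_of <- function(pos, window_size = 5e5) {
  as.integer((pos - 1) %/% window_size + 1)
}

#' Call iHS selection-signature regions from windowed extreme-SNP counts
#'
#' A window is called when it contains at least `min_snps` scored SNPs of
#' which at least `min_extreme` are extreme; adjacent called windows on the
#' same chromosome are merged into a single region. The peak SNP is the
#' scored SNP with the largest `|iHS|` in the region.
#'
#' @param ihs_table An [ihs_scan()] result.
#' @param window_size Window width in bp (default 500 kb).
#' @param min_snps Minimum scored SNPs per window (default 10).
#' @param min_extreme Minimum extreme SNPs per window (default 5).
#' @return Data frame of regions: `method` (`"iHS"`), `chrom`, `start`,
#'   `end`, `n_snps`, `n_extreme`, `peak_snp`, `peak_pos`, `peak_value`.
#' @export
call_ihs_regions <- function(ihs_table, window_size = 5e5, min_snps = 10L,
                             min_extreme = 5L) {
  scored <- ihs_table[!is.na(ihs_table$ihs), , drop = FALSE]
  empty <- data.frame(method = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), n_extreme = integer(),
                      peak_snp = character(), peak_pos = numeric(),
                      peak_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(scored) == 0L) return(empty)
  scored$window <- window_of(scored$pos, window_size)
  key <- paste(scored$chrom, scored$window)
  n_snps <- tapply(scored$snp, key, length)
  n_ext <- tapply(scored$extreme, key, sum)
  called <- names(n_snps)[n_snps >= min_snps & n_ext >= min_extreme]
  if (length(called) == 0L) return(empty)

  parts <- do.call(rbind, strsplit(called, " "))
  cw <- data.frame(chrom = parts[, 1L], window = as.integer(parts[, 2L]),
                   stringsAsFactors = FALSE)
  cw <- cw[order(chrom_rank(cw$chrom), cw$window), , drop = FALSE]
  ## merge runs of adjacent called windows per chromosome
  new_block <- c(TRUE, !(cw$chrom[-1L] == cw$chrom[-nrow(cw)] &
                         cw$window[-1L] == cw$window[-nrow(cw)] + 1L))
  cw$block <- cumsum(new_block)
  out <- lapply(split(cw, cw$block), function(b) {
    start <- (min(b$window) - 1) * window_size + 1
    end <- max(b$window) * window_size
    in_r <- scored$chrom == b$chrom[1L] & scored$window %in% b$window
    reg <- scored[in_r, , drop = FALSE]
    peak <- which.max(reg$abs_ihs)
    data.frame(method = "iHS", chrom = b$chrom[1L], start = start,
               end = end, n_snps = nrow(reg),
               n_extreme = sum(reg$extreme),
               peak_snp = reg$snp[peak], peak_pos = reg$pos[peak],
               peak_value = reg$abs_ihs[peak], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Build a GRanges from a region data frame (1-based closed coordinates).
.regions_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end))
}

#' Intersect two region lists
#'
#' Pairwise intersections (>= 1 bp, same chromosome) between two sets of
#' called regions, reported with intersection coordinates — used to find
#' signatures supported by both the iHS and the ROH approach.
#'
#' @param regions_a,regions_b Region data frames with `chrom`, `start`,
#'   `end` (1-based closed).
#' @return Data frame: `method` (`"overlap"`), `chrom`, `start`, `end`,
#'   `idx_a`, `idx_b` (row indices of the contributing regions).
#' @export
overlap_regions <- function(regions_a, regions_b) {
  empty <- data.frame(method = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      idx_a = integer(), idx_b = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(regions_a) == 0L || nrow(regions_b) == 0L) return(empty)
  ga <- .regions_gr(regions_a)
  gb <- .regions_gr(regions_b)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  if (length(hits) == 0L) return(empty)
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  inter <- GenomicRanges::pintersect(ga[qa], gb[qb])
  data.frame(method = "overlap",
             chrom = as.character(GenomicRanges::seqnames(inter)),
             start = GenomicRanges::start(inter),
             end = GenomicRanges::end(inter),
             idx_a = qa, idx_b = qb, stringsAsFactors = FALSE)
}

#' Read a BED interval file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based closed convention on read (`start + 1`, `end`). Columns beyond
#' the fourth are ignored; a missing name column is filled with
#' `interval_<n>`.
#'
#' @param path Path to a BED file (>= 3 tab- or space-separated columns).
#' @return Data frame: `chrom`, `start`, `end` (1-based closed), `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) &
                 !grepl("^(track|browser|#)", lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      stop("malformed BED line ", i, ": bad interval [", f[2L], ", ", f[3L], ")")
    }
    out[[i]] <- data.frame(chrom = f[1L], start = s + 1, end = e,
                           name = if (length(f) >= 4L) f[4L] else
                             sprintf("interval_%d", i),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write regions as a BED file
#'
#' Converts the package's 1-based closed intervals back to BED's 0-based
#' half-open convention (`start - 1`, `end`).
#'
#' @param regions Region data frame (`chrom`, `start`, `end`, optionally a
#'   name column such as `peak_snp`).
#' @param path Output path.
#' @param name_col Column used for the BED name field (default: `method` if
#'   present, else a running index).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path, name_col = NULL) {
  name <- if (!is.null(name_col)) regions[[name_col]]
          else regions$method %||% sprintf("region_%d", seq_len(nrow(regions)))
  df <- data.frame(regions$chrom,
                   format(regions$start - 1, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Annotate regions against an interval file
#'
#' Attaches to every region the names of BED intervals overlapping it by at
#' least 1 bp (after BED's half-open coordinates are converted on read; an
#' interval merely abutting a region does not overlap).
#'
#' @param regions Region data frame (`chrom`, `start`, `end`).
#' @param bed A BED file path, or a data frame as returned by [read_bed()].
#' @return `regions` with added columns `annotations` (comma-separated
#'   names, `""` if none) and `n_annotations`.
#' @export
annotate_intervals <- function(regions, bed) {
  if (is.character(bed)) bed <- read_bed(bed)
  regions$annotations <- rep("", nrow(regions))
  regions$n_annotations <- rep(0L, nrow(regions))
  if (nrow(regions) == 0L || nrow(bed) == 0L) return(regions)
  gr <- .regions_gr(regions)
  gb <- .regions_gr(bed)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, gb))
  if (length(hits) > 0L) {
    ann <- tapply(bed$name[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  paste, collapse = ",")
    idx <- as.integer(names(ann))
    regions$annotations[idx] <- unname(ann)
    cnt <- tapply(S4Vectors::subjectHits(hits),
                  S4Vectors::queryHits(hits), length)
    regions$n_annotations[idx] <- as.integer(cnt)
  }
  regions
}
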