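#' Read a signal profile from disk
#'
#' Two dialects are supported. `"plain"` is one numeric value per line, one
#' bin per value. `"bedgraph"` is 4-column tab- or space-delimited
#' (chrom, start, end, value) with equal-width, non-overlapping, sorted
#' bins; the bin width is inferred from the first row of each chromosome
#' and enforced for every row. `"auto"` sniffs the first non-comment line.
#'
#' Multi-chromosome bedGraph input decomposes into one profile per
#' chromosome; segmentation never crosses a chromosome boundary.
#'
#' @param path path to the input file.
#' @param format `"auto"`, `"plain"`, or `"bedgraph"`.
#' @param na_action `"error"` (default) rejects missing values;
#'   `"fill"` replaces them with `mu0`. The sampling model assumes a
#'   complete sequence, and silent imputation would distort the robust
#'   noise estimate, so filling is opt-in.
#' @param mu0 value used when `na_action = "fill"`.
#' @param name profile name; defaults to the file name.
#' @return A `segscan_profile`, or a named list of them (one per
#'   chromosome) when the input spans several chromosomes.
#' @export
read_profile <- function(path, format = c("auto", "plain", "bedgraph"),
                         na_action = c("error", "fill"), mu0 = 0,
                         name = basename(path)) {
  format <- match.arg(format)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (!length(lines)) stop("empty profile file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (length(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]) >= 4L)
      "bedgraph" else "plain"
  }
  if (format == "plain") {
    vals <- suppressWarnings(as.numeric(trimws(lines)))
    bad <- which(is.na(vals) & !toupper(trimws(lines)) %in% c("NA", "NAN"))
    if (length(bad))
      stop(sprintf("non-numeric value at line %d: '%s'", bad[1L],
                   lines[bad[1L]]), call. = FALSE)
    vals <- .fill_na(vals, na_action, mu0, path)
    return(signal_profile(vals, name = name))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("bedgraph line %d has %d fields (4 required)",
                 which(nf < 4L)[1L], nf[which(nf < 4L)[1L]]), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  val_chr <- vapply(fields, `[[`, "", 4L)
  value <- suppressWarnings(as.numeric(val_chr))
  bad <- which(is.na(start) | is.na(end) |
                 (is.na(value) & !toupper(val_chr) %in% c("NA", "NAN")))
  if (length(bad))
    stop(sprintf("non-numeric field at line %d: '%s'", bad[1L],
                 lines[bad[1L]]), call. = FALSE)
  out <- lapply(split(seq_along(chrom), factor(chrom, unique(chrom))),
                function(i) {
    s <- start[i]; e <- end[i]; v <- value[i]; cn <- chrom[i][1L]
    if (is.unsorted(s, strictly = TRUE))
      stop("bedgraph rows must be sorted by start within ", cn,
           call. = FALSE)
    w <- e - s
    if (any(w != w[1L]))
      stop(sprintf("unequal bin widths on %s: %d then %d", cn, as.integer(w[1L]),
                   as.integer(w[w != w[1L]][1L])), call. = FALSE)
    if (w[1L] < 1) stop("non-positive bin width on ", cn, call. = FALSE)
    if (any(s[-1L] < e[-length(e)]))
      stop("overlapping bins on ", cn, call. = FALSE)
    if (any(s[-1L] != e[-length(e)]))  {
      if (na_action == "error")
        stop("gapped bins on ", cn, "; profiles must cover a contiguous ",
             "range (pass na_action = \"fill\" to pad gaps with mu0)",
             call. = FALSE)
      if (any((s - s[1L]) %% w[1L] != 0))
        stop("gaps on ", cn, " are not multiples of the bin width",
             call. = FALSE)
      idx <- (s - s[1L]) / w[1L] + 1L
      full <- rep(mu0, idx[length(idx)])
      full[idx] <- v
      v <- full
    }
    v <- .fill_na(v, na_action, mu0, path)
    signal_profile(v, chrom = cn, bin_start = s[1L], bin_width = w[1L],
                   name = name)
  })
  if (length(out) == 1L) out[[1L]] else out
}

.fill_na <- function(v, na_action, mu0, path) {
  if (anyNA(v)) {
    if (na_action == "error")
      stop("missing values in ", path,
           "; pass na_action = \"fill\" to replace them with mu0",
           call. = FALSE)
    v[is.na(v)] <- mu0
  }
  v
}

#' Write segment calls as BED tracks
#'
#' Writes one BED6 file per biological-cutoff tier plus one unfiltered
#' file. Rows are `chrom start end name score strand` with 0-based
#' half-open coordinates, score `-10 log10(p)` clamped to \[0, 1000\],
#' and strand `+` for segments above the null mean, `-` below. Profiles
#' without genomic coordinates are written with bin indices as
#' coordinates. Tier files are nested: a segment appears in every tier
#' whose cutoff it passes.
#'
#' @param result a `segscan_result` from [segment_profile()].
#' @param profile the profile that was segmented.
#' @param prefix output path prefix; files are `<prefix>.bed` and
#'   `<prefix>.bc<tier>.bed`.
#' @return Invisibly, the paths written.
#' @export
write_segments <- function(result, profile, prefix) {
  stopifnot(inherits(result, "segscan_result"))
  seg <- result$segments
  if (nrow(seg) > 1L) {
    o <- order(seg$start)
    if (any(seg$start[o][-1L] < seg$end[o][-nrow(seg)]))
      stop("segments overlap; write_segments requires a disjoint set",
           call. = FALSE)
    seg <- seg[o, , drop = FALSE]
  }
  chrom <- if (!is.null(profile$chrom)) profile$chrom else "seq"
  bw <- profile$bin_width
  b0 <- profile$bin_start
  bed <- data.frame(
    chrom = rep(chrom, nrow(seg)),
    start = b0 + seg$start * bw,
    end = b0 + seg$end * bw,
    name = if (nrow(seg)) sprintf("seg%04d", seq_len(nrow(seg))) else character(0),
    score = .bed_score(seg$z),
    strand = ifelse(seg$mean >= result$noise$mu0, "+", "-"),
    stringsAsFactors = FALSE
  )
  paths <- c(paste0(prefix, ".bed"),
             paste0(prefix, ".bc", format(result$config$bc_tiers), ".bed"))
  .write_bed(bed, paths[1L])
  tiers <- result$tier_membership
  for (j in seq_along(result$config$bc_tiers))
    .write_bed(bed[tiers[, j], , drop = FALSE], paths[j + 1L])
  invisible(paths)
}

# -10 log10(p) from z, computed on the log scale so that extreme segments
# (where p underflows) still get a finite, correctly clamped score
.bed_score <- function(z) {
  if (!length(z)) return(integer(0))
  log10p <- (stats::pnorm(-abs(z), log.p = TRUE) + log(2)) / log(10)
  pmin(1000L, pmax(0L, as.integer(round(-10 * log10p))))
}

.write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read intervals from a BED file
#'
#' Reads the first three columns of a BED file into a data frame of
#' 0-based half-open intervals, optionally converting genomic coordinates
#' back to bin indices of a given profile.
#'
#' @param path BED file path.
#' @param profile if supplied, coordinates are mapped to bin indices using
#'   the profile's `bin_start` and `bin_width`.
#' @return data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed_intervals <- function(path, profile = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  out <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(profile)) {
    out$start <- (out$start - profile$bin_start) / profile$bin_width
    out$end <- (out$end - profile$bin_start) / profile$bin_width
  }
  out
}

#' Write a profile as bedGraph
#'
#' @param profile a `segscan_profile`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(profile, path) {
  n <- length(profile$values)
  chrom <- if (!is.null(profile$chrom)) profile$chrom else "seq"
  starts <- profile$bin_start + (seq_len(n) - 1L) * profile$bin_width
  df <- data.frame(chrom = chrom, start = starts,
                   end = starts + profile$bin_width,
                   value = sprintf("%.17g", profile$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
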