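BASES <- c("A", "T", "C", "G")
SEXTET <- c("A", "T", "C", "G", "N", "del")

#' Parse one line of a sync file
#'
#' The sync format (popoolation2 dialect) carries one locus per line:
#' chromosome, 1-based position, reference base, then one
#' `A:T:C:G:N:del` count sextet per sample. Sample columns are ordered
#' by the replicate/time layout declared in the run configuration (see
#' [sync_layout()]).
#'
#' @param line A single whitespace-separated sync line.
#' @param line_number Optional line number used in error messages.
#' @return An object of class `sync_record`: list with `chrom`, `pos`,
#'   `ref` and `counts` (samples x 6 integer matrix, columns
#'   A,T,C,G,N,del).
#' @examples
#' parse_sync_line("2L 5002 A 10:0:0:5:0:0 8:0:0:7:0:0")
#' @export
parse_sync_line <- function(line, line_number = NA_integer_) {
  where <- if (is.na(line_number)) "" else sprintf(" (line %d)", line_number)
  fields <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(fields) < 4L)
    stop(sprintf("sync format error%s: expected >= 4 columns, got %d",
                 where, length(fields)))
  pos <- suppressWarnings(as.integer(fields[2L]))
  if (is.na(pos) || pos < 1L)
    stop(sprintf("sync format error%s, column 2: position '%s' is not a positive integer",
                 where, fields[2L]))
  ref <- fields[3L]
  if (!ref %in% c(BASES, "N"))
    stop(sprintf("sync format error%s, column 3: reference base '%s' not in A,T,C,G,N",
                 where, ref))
  sext <- fields[-(1:3)]
  ok <- grepl("^\\d+:\\d+:\\d+:\\d+:\\d+:\\d+$", sext)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("sync format error%s, column %d: malformed count sextet '%s'",
                 where, bad + 3L, sext[bad]))
  }
  counts <- matrix(as.integer(unlist(strsplit(sext, ":", fixed = TRUE))),
                   ncol = 6L, byrow = TRUE, dimnames = list(NULL, SEXTET))
  structure(list(chrom = fields[1L], pos = pos, ref = ref, counts = counts),
            class = "sync_record")
}

#' Read a sync file
#'
#' @param path Path to a sync file; blank lines and lines starting with
#'   `#` are skipped.
#' @return A list of [parse_sync_line()] records.
#' @export
read_sync <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  lapply(keep, function(i) parse_sync_line(lines[i], i))
}

#' Write sync records to a file
#'
#' Inverse of [parse_sync_line()]; `parse(write(x))` round-trips
#' exactly.
#'
#' @param records A list of `sync_record` objects.
#' @param path Output path.
#' @export
write_sync <- function(records, path) {
  lines <- vapply(records, function(rec) {
    sext <- apply(rec$counts, 1L, paste, collapse = ":")
    paste(c(rec$chrom, rec$pos, rec$ref, sext), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Sample-column layout of a sync file
#'
#' Sync files carry no metadata on how their sample columns map to
#' (replicate, time point); the mapping must be declared. The default
#' `"time_major"` layout lists all replicates for the first time point,
#' then all replicates for the second, and so on (t0 r1..rR, t1
#' r1..rR, ...); `"replicate_major"` lists each replicate's full time
#' course in turn.
#'
#' @param replicates Number of replicate populations R.
#' @param time_points Number of sampled time points T.
#' @param order `"time_major"` (default) or `"replicate_major"`.
#' @return An object of class `sync_layout` with a `replicate` and
#'   `time` index for each of the R*T sample columns.
#' @export
sync_layout <- function(replicates, time_points,
                        order = c("time_major", "replicate_major")) {
  order <- match.arg(order)
  if (replicates < 1L || time_points < 1L)
    stop("'replicates' and 'time_points' must be positive")
  k <- seq_len(replicates * time_points) - 1L
  if (order == "time_major") {
    r <- k %% replicates + 1L
    t <- k %/% replicates + 1L
  } else {
    r <- k %/% time_points + 1L
    t <- k %% time_points + 1L
  }
  structure(list(replicates = as.integer(replicates),
                 time_points = as.integer(time_points),
                 order = order, replicate = r, time = t),
            class = "sync_layout")
}

#' Focal-allele counts and depths for one locus
#'
#' The container consumed by the likelihood: focal-allele read counts
#' `focal[r, t]` and total depths `coverage[r, t]` per replicate and
#' time point, plus the sampling `generations` (non-negative, strictly
#' increasing, first entry 0 by convention).
#'
#' @param chrom,pos Locus coordinates (1-based).
#' @param focal,coverage Integer R x T matrices with
#'   `focal <= coverage` elementwise.
#' @param generations Numeric vector of length T, strictly increasing.
#' @param focal_allele,ref Optional base labels kept for bookkeeping.
#' @return An object of class `locus_counts`.
#' @export
locus_counts <- function(chrom, pos, focal, coverage, generations,
                         focal_allele = NA_character_, ref = NA_character_) {
  focal <- as.matrix(focal); coverage <- as.matrix(coverage)
  if (!identical(dim(focal), dim(coverage)))
    stop("'focal' and 'coverage' must have identical dimensions")
  if (ncol(focal) != length(generations))
    stop("number of time points must match 'generations'")
  if (any(focal < 0) || any(coverage < 0) || any(focal > coverage))
    stop("need 0 <= focal <= coverage for every sample")
  if (length(generations) > 1L && any(diff(generations) <= 0))
    stop("'generations' must be strictly increasing")
  structure(list(chrom = chrom, pos = pos, focal = focal, coverage = coverage,
                 generations = as.numeric(generations),
                 focal_allele = focal_allele, ref = ref),
            class = "locus_counts")
}

#' Reduce a sync record to biallelic focal-allele counts
#'
#' The model is strictly biallelic, so each locus is reduced to a focal
#' allele versus the reference base. The focal allele is the
#' non-reference base (among A,T,C,G) with the largest count summed
#' over all samples; ties break in fixed A,T,C,G order. Depth is focal
#' plus reference reads: third alleles, N and del counts never enter
#' the coverage.
#'
#' @param rec A `sync_record`.
#' @param layout A [sync_layout()] consistent with the record's sample
#'   count.
#' @param generations Sampling times in generations (length
#'   `layout$time_points`).
#' @return A [locus_counts()] object.
#' @export
to_locus_counts <- function(rec, layout, generations) {
  ns <- nrow(rec$counts)
  if (ns != layout$replicates * layout$time_points)
    stop(sprintf("locus %s:%d has %d samples but layout declares %d x %d",
                 rec$chrom, rec$pos, ns, layout$replicates, layout$time_points))
  ref <- if (rec$ref %in% BASES) rec$ref else BASES[which.max(colSums(rec$counts[, BASES, drop = FALSE]))]
  alts <- setdiff(BASES, ref)
  totals <- colSums(rec$counts[, alts, drop = FALSE])
  focal_allele <- alts[which.max(totals)]   # which.max: first wins on ties (A,T,C,G order)
  fc <- rec$counts[, focal_allele]
  cov <- fc + rec$counts[, ref]
  R <- layout$replicates; Tn <- layout$time_points
  fm <- matrix(0L, R, Tn); cm <- matrix(0L, R, Tn)
  fm[cbind(layout$replicate, layout$time)] <- fc
  cm[cbind(layout$replicate, layout$time)] <- cov
  locus_counts(rec$chrom, rec$pos, fm, cm, generations,
               focal_allele = focal_allele, ref = ref)
}

RESULT_COLUMNS <- c("chrom", "pos", "mean_sigma", "log_BF", "alpha", "beta",
                    "filtered", "degenerate")

#' Write per-locus results to a tab-separated table
#'
#' One row per locus in input order. Loci removed by the variance
#' pre-filter are retained for bookkeeping with `filtered = 1` and `NA`
#' statistics; degenerate gamma fits keep their (invalid) shape/rate for
#' diagnosis but carry `NA` summaries and `degenerate = 1`.
#'
#' @param results A list of `locus_result` objects (see
#'   [analyse_locus()]) or a data frame with the result columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_to_df(results)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

results_to_df <- function(results) {
  if (length(results) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(RESULT_COLUMNS)),
                                 RESULT_COLUMNS))
    df$chrom <- character(0)
    return(df)
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(chrom = r$chrom, pos = r$pos,
               mean_sigma = r$mean_sigma, log_BF = r$log_bf,
               alpha = r$alpha, beta = r$beta,
               filtered = as.integer(r$filtered),
               degenerate = as.integer(r$degenerate))
  }))
}

#' Read a results table written by [write_results()]
#' @param path Path to a results TSV.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character"), na.strings = "NA")
}
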