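#' Rescaled-average degradation baseline
#'
#' The baseline against which "high intensity" is defined is an exponential
#' rescaling of the regime's total average reactivity along the molecule:
#' `IA(N) = A * (1 + q)^N`, where `A` is the total average degradation
#' reactivity obtained from the comprehensive stress gradient, `q` a small
#' dimensionless rescale factor, and `N` the 1-based nucleotide position.
#'
#' @param A Total average degradation reactivity (> 0, arbitrary units).
#' @param q Rescale factor (>= 0, dimensionless).
#' @param regime Label for the stress regime the parameters belong to.
#' @return An object of class `degradation_baseline`.
#' @export
#' @examples
#' b <- degradation_baseline(3.5, 0.000001, "freeze_thaw")
#' baseline_at(b, 0)
degradation_baseline <- function(A, q, regime = "unspecified") {
  if (!is.numeric(A) || A <= 0) abort("A must be positive")
  if (!is.numeric(q) || q < 0) abort("q must be nonnegative")
  structure(list(A = A, q = q, regime = regime),
            class = "degradation_baseline")
}

#' @export
print.degradation_baseline <- function(x, ...) {
  cat(sprintf("<degradation_baseline> %s: IA(N) = %g * (1 + %g)^N\n",
              x$regime, x$A, x$q))
  invisible(x)
}

#' @method tidy degradation_baseline
#' @export
tidy.degradation_baseline <- function(x, ...) {
  tibble(term = c("A", "q"),
         estimate = c(x$A, x$q),
         regime = x$regime)
}

#' @method glance degradation_baseline
#' @export
glance.degradation_baseline <- function(x, ...) {
  tibble(A = x$A, q = x$q, regime = x$regime)
}

#' Evaluate the baseline at position N
#'
#' @param baseline A [degradation_baseline()].
#' @param N Nonnegative integer position(s).
#' @return `A * (1 + q)^N`, vectorized over `N`.
#' @export
baseline_at <- function(baseline, N) {
  stopifnot(inherits(baseline, "degradation_baseline"))
  if (any(N < 0)) abort("N must be nonnegative", class = "mprtseq_input_error")
  baseline$A * (1 + baseline$q)^N
}

#' Classify positions as high-intensity
#'
#' A position is high-intensity when its reactivity strictly exceeds the
#' baseline evaluated at that position; ties and missing values are low.
#'
#' @param profile A reactivity profile.
#' @param baseline A [degradation_baseline()].
#' @return A tibble with columns `position`, `high` (logical).
#' @export
classify_high_intensity <- function(profile, baseline) {
  thr <- baseline_at(baseline, profile$position)
  high <- !is.na(profile$reactivity) & profile$reactivity > thr
  tibble(position = profile$position, high = high)
}

#' Call degradation hotspots across stress conditions
#'
#' Within each condition, high-intensity positions lying within `max_gap`
#' nucleotides of each other are merged into runs. Runs from different
#' conditions that overlap are merged into candidate calls; a call is kept
#' only if every required condition contributes at least `min_high` high
#' positions inside it. The reported span is clipped to the outermost high
#' positions (over all conditions) in the call.
#'
#' @param mask_by_condition Named list of high-intensity masks (from
#'   [classify_high_intensity()]), one per condition; masks share indexing.
#' @param min_high Minimum high positions per condition per call.
#' @param max_gap Largest distance (nt) between successive high positions
#'   merged into one run.
#' @param require_all_conditions If `TRUE` (default) a call must be
#'   supported by every condition; if `FALSE`, by at least one.
#' @param construct Optional [mrna_construct()]; adds the spanned sequence.
#' @return A tibble of class `hotspot_calls` with columns `start`, `end`,
#'   `width`, per-condition high counts (`n_high_<condition>`), and
#'   `sequence` when a construct is given; sorted by `start`.
#' @export
find_hotspots <- function(mask_by_condition, min_high = 2, max_gap = 3,
                          require_all_conditions = TRUE, construct = NULL) {
  if (length(mask_by_condition) == 0L) {
    abort("at least one condition mask is required",
          class = "mprtseq_config_error")
  }
  if (is.null(names(mask_by_condition)) ||
      any(names(mask_by_condition) == "")) {
    names(mask_by_condition) <- paste0("condition",
                                       seq_along(mask_by_condition))
  }
  conditions <- sort(names(mask_by_condition))  # order-invariant
  runs <- purrr::map(mask_by_condition[conditions], function(m) {
    merge_runs(m$position[m$high], max_gap)
  })
  all_runs <- dplyr::bind_rows(runs, .id = "condition")
  empty <- tibble(start = integer(0), end = integer(0), width = integer(0))
  if (nrow(all_runs) == 0L) return(new_hotspots(empty, conditions, construct))

  # connected components of overlapping runs across conditions
  all_runs <- all_runs |> arrange(.data$start, .data$end)
  comp <- integer(nrow(all_runs))
  cur <- 0L
  cur_end <- -Inf
  for (i in seq_len(nrow(all_runs))) {
    if (all_runs$start[i] > cur_end) cur <- cur + 1L
    comp[i] <- cur
    cur_end <- max(cur_end, all_runs$end[i])
  }
  all_runs$component <- comp

  highs <- purrr::map(mask_by_condition[conditions],
                      function(m) m$position[m$high])
  calls <- all_runs |>
    group_by(.data$component) |>
    summarise(start = min(.data$start), end = max(.data$end),
              conds = list(unique(.data$condition)), .groups = "drop")
  keep <- logical(nrow(calls))
  counts <- matrix(0L, nrow(calls), length(conditions),
                   dimnames = list(NULL, conditions))
  for (i in seq_len(nrow(calls))) {
    n_in <- vapply(conditions, function(cn) {
      sum(highs[[cn]] >= calls$start[i] & highs[[cn]] <= calls$end[i])
    }, integer(1))
    counts[i, ] <- n_in
    keep[i] <- if (require_all_conditions) all(n_in >= min_high)
               else any(n_in >= min_high)
  }
  calls <- calls[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  if (nrow(calls) == 0L) return(new_hotspots(empty, conditions, construct))
  # clip spans to outermost high positions over all conditions
  for (i in seq_len(nrow(calls))) {
    hs <- unlist(lapply(highs, function(h) {
      h[h >= calls$start[i] & h <= calls$end[i]]
    }), use.names = FALSE)
    calls$start[i] <- min(hs)
    calls$end[i] <- max(hs)
  }
  out <- tibble(start = as.integer(calls$start),
                end = as.integer(calls$end),
                width = as.integer(calls$end - calls$start + 1L))
  for (j in seq_along(conditions)) {
    out[[paste0("n_high_", conditions[j])]] <- counts[, j]
  }
  out <- out |> arrange(.data$start)
  new_hotspots(out, conditions, construct)
}

merge_runs <- function(pos, max_gap) {
  if (length(pos) == 0L) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  pos <- sort(pos)
  brk <- c(TRUE, diff(pos) > max_gap)
  grp <- cumsum(brk)
  tibble(start = as.integer(tapply(pos, grp, min)),
         end = as.integer(tapply(pos, grp, max)))
}

new_hotspots <- function(tb, conditions, construct) {
  if (!is.null(construct) && nrow(tb) > 0) {
    tb$sequence <- vapply(seq_len(nrow(tb)), function(i) {
      substr(construct$sequence, tb$start[i], tb$end[i])
    }, character(1))
  }
  structure(tb, conditions = conditions,
            class = c("hotspot_calls", class(tb)))
}

#' Fold change of a window against a reference average
#'
#' Mean reactivity over `[start, end]` divided by an explicit reference
#' average (e.g. the regime's total average reactivity). The reference is
#' never inferred from the profile.
#'
#' @param profile A reactivity profile.
#' @param start,end Window bounds, 1-based inclusive.
#' @param reference_average Positive reference reactivity.
#' @return A scalar fold change.
#' @export
fold_change <- function(profile, start, end, reference_average) {
  stopifnot(start <= end, reference_average > 0)
  v <- profile$reactivity[profile$position >= start & profile$position <= end]
  if (all(is.na(v))) abort("window contains no non-missing reactivities",
                           class = "mprtseq_input_error")
  mean(v, na.rm = TRUE) / reference_average
}

#' Base composition of high-intensity positions
#'
#' @param mask A high-intensity mask (tibble with `position`, `high`).
#' @param sequence RNA sequence string the mask indexes into.
#' @return A tibble with columns `base`, `count`, `proportion` (rows for
#'   A, C, G, U always present) and attribute `n_high`; when no position is
#'   high, proportions are `NA` and the result carries `n_high = 0`.
#' @export
composition_stats <- function(mask, sequence) {
  bases <- strsplit(sequence, "")[[1]]
  if (nrow(mask) != length(bases)) {
    abort("mask and sequence lengths differ", class = "mprtseq_input_error")
  }
  hi <- bases[mask$position[mask$high]]
  counts <- unname(vapply(c("A", "C", "G", "U"),
                          function(b) sum(hi == b), integer(1)))
  n <- sum(counts)
  tb <- tibble(base = c("A", "C", "G", "U"),
               count = counts,
               proportion = if (n > 0) counts / n else rep(NA_real_, 4))
  structure(tb, n_high = n)
}

#' Export hotspot calls
#'
#' `write_hotspots_tsv()` writes the call table as-is (1-based inclusive);
#' `write_hotspots_bed()` writes BED6 (0-based half-open);
#' `write_hotspots_json()` writes the full per-condition detail.
#'
#' @param calls A [find_hotspots()] table.
#' @param path Output path.
#' @param name Chromosome/sequence name for BED output.
#' @export
write_hotspots_tsv <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path)
  invisible(path)
}

#' @rdname write_hotspots_tsv
#' @export
write_hotspots_bed <- function(calls, path, name = "mRNA") {
  bed <- tibble(
    chrom = name,
    chromStart = calls$start - 1L,  # 0-based half-open
    chromEnd = calls$end,
    name = paste0("hotspot_", seq_len(nrow(calls))),
    score = 0L,
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_hotspots_tsv
#' @export
write_hotspots_json <- function(calls, path) {
  payload <- list(conditions = attr(calls, "conditions"),
                  calls = as_tibble(calls))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
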