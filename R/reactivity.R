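#' Map a per-primer peak table onto template positions
#'
#' A cDNA of length *k* read from a primer pairing at
#' `pairing_start..pairing_end` terminated at template position
#' `pairing_start - k`: the RT stop marks a chain break at that position.
#' Intensities landing on the same position are summed.
#'
#' @param peak_table Data frame with columns `cdna_length`, `intensity`
#'   (e.g. one element of [simulate_rt_traces()], or a table read from CSV).
#' @param primer A single-row primer table (or an [rt_primer_panel()] row)
#'   with `pairing_start`.
#' @return A tibble with columns `position`, `intensity`, sorted by
#'   position.
#' @export
peaks_to_positions <- function(peak_table, primer) {
  ps <- as.integer(primer$pairing_start[1])
  pt <- as_tibble(peak_table)
  if (nrow(pt) == 0L) return(tibble(position = integer(0), intensity = numeric(0)))
  if (any(pt$cdna_length >= ps)) {
    abort(sprintf(
      "cDNA length >= pairing_start (%d): stop position would fall inside or 3' of the primer site",
      ps), class = "mprtseq_coordinate_error")
  }
  if (any(pt$cdna_length < 1L)) abort("cDNA lengths must be >= 1 nt")
  pt |>
    mutate(position = ps - as.integer(.data$cdna_length)) |>
    group_by(.data$position) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    arrange(.data$position)
}

#' Assemble per-primer position maps into one profile
#'
#' Each primer contributes only the positions inside its own section of the
#' section map; contributions outside it (reads running past the adjacent
#' primer's territory) are discarded. Positions read by no primer - primer
#' footprints at section joints and everything 3' of the last pairing start
#' - are reported as missing (`NA`), not zero.
#'
#' @param per_primer_maps Named list of `position`/`intensity` tibbles, one
#'   per primer, named as in the section map.
#' @param section_map A [build_section_map()] result.
#' @param construct Optional [mrna_construct()]; if given, a `base` column
#'   is added.
#' @param treatment Treatment label recorded on the profile.
#' @return A tibble of class `reactivity_profile` with columns `position`,
#'   `reactivity`, `section`, and optionally `base`; indexed 1..L.
#' @export
assemble_sections <- function(per_primer_maps, section_map,
                              construct = NULL, treatment = "unknown") {
  L <- attr(section_map, "construct_length")
  stopifnot(!is.null(L))
  missing_primers <- setdiff(section_map$primer, names(per_primer_maps))
  if (length(missing_primers) > 0) {
    abort(paste0("no position map supplied for primer(s): ",
                 paste(missing_primers, collapse = ", ")))
  }
  reactivity <- rep(NA_real_, L)
  owner <- rep(NA_character_, L)
  for (i in seq_len(nrow(section_map))) {
    nm <- section_map$primer[i]
    lo <- section_map$start[i]
    hi <- section_map$end[i]
    m <- per_primer_maps[[nm]]
    if (is.null(m) || nrow(m) == 0L) next
    keep <- m$position >= lo & m$position <= hi
    pos <- m$position[keep]
    dup <- pos[!is.na(owner[pos]) & owner[pos] != nm]
    if (length(dup) > 0) {
      abort(sprintf("assembly conflict: position %d claimed by two primers",
                    dup[1]), class = "mprtseq_assembly_conflict")
    }
    reactivity[pos] <- ifelse(is.na(reactivity[pos]), 0, reactivity[pos]) +
      m$intensity[keep]
    owner[pos] <- nm
  }
  # positions inside a section but with no observed stop: zero signal, owned
  for (i in seq_len(nrow(section_map))) {
    idx <- section_map$start[i]:section_map$end[i]
    blank <- idx[is.na(owner[idx])]
    if (!is.null(per_primer_maps[[section_map$primer[i]]])) {
      reactivity[blank] <- ifelse(is.na(reactivity[blank]), 0, reactivity[blank])
      owner[blank] <- section_map$primer[i]
    }
  }
  prof <- tibble(position = seq_len(L),
                 reactivity = reactivity,
                 section = owner)
  if (!is.null(construct)) {
    prof$base <- strsplit(construct$sequence, "")[[1]]
    prof <- prof[, c("position", "base", "reactivity", "section")]
  }
  new_profile(prof, treatment = treatment)
}

new_profile <- function(prof, treatment = "unknown", normalization = NULL,
                        clamped = NULL) {
  structure(as_tibble(prof),
            treatment = treatment,
            normalization = normalization,
            clamped = clamped,
            class = c("reactivity_profile", class(as_tibble(prof))))
}

#' Per-section normalization factors (2%/8% box-plot rule)
#'
#' For each section, the factor is the mean of the 8% of values that sit
#' just below the top 2% (the top 2% are treated as outliers and excluded).
#' This is the standard box-plot scaling for primer-extension reactivity
#' data; dividing by the factor puts typical high reactivities near 1.
#'
#' With `robust = TRUE` (used by the pipeline on sparse simulated counts)
#' degenerate sections do not error: an all-zero section gets factor 1 and a
#' section whose trimmed top mean is zero (fewer positive values than the
#' excluded 2%) falls back to the mean of its positive values.
#'
#' @param profile A [assemble_sections()] profile.
#' @param per_section Compute one factor per section (default) or a single
#'   global factor.
#' @param robust Fall back instead of erroring on degenerate sections.
#' @return A tibble with columns `section`, `factor`, `n`.
#' @export
normalization_factors <- function(profile, per_section = TRUE,
                                  robust = FALSE) {
  vals <- profile$reactivity
  ok <- !is.na(vals)
  if (sum(ok) < 10L) abort("need at least 10 non-missing positions")
  groups <- if (per_section) profile$section else rep("global", nrow(profile))
  tb <- tibble(section = groups[ok], value = vals[ok]) |>
    group_by(.data$section) |>
    summarise(factor = boxplot_factor(.data$value, .data$section[1],
                                      robust = robust),
              n = dplyr::n(), .groups = "drop")
  tb
}

boxplot_factor <- function(v, section_name, robust = FALSE) {
  if (all(v == 0)) {
    if (robust) return(1)
    abort(sprintf("section '%s' is all zero: cannot normalize", section_name),
          class = "mprtseq_normalization_error")
  }
  vs <- sort(v, decreasing = TRUE)
  n <- length(vs)
  n_excl <- ceiling(0.02 * n)
  n_avg <- max(1L, ceiling(0.08 * n))
  top <- vs[(n_excl + 1):min(n, n_excl + n_avg)]
  f <- mean(top)
  if (f <= 0) {
    if (robust) return(mean(v[v > 0]))
    abort(sprintf("section '%s': normalization factor is not positive",
                  section_name), class = "mprtseq_normalization_error")
  }
  f
}

#' Normalize a reactivity profile
#'
#' Divides each position by its section's normalization factor. By default
#' the factors come from the profile itself; pass `factors` computed on a
#' pooled gradient (see [normalization_factors()]) to scale several
#' treatments onto one comparable scale.
#'
#' @param profile A reactivity profile.
#' @param factors Optional factor table from [normalization_factors()].
#' @param per_section Passed to [normalization_factors()] when `factors` is
#'   `NULL`.
#' @return The normalized profile, with the factor table recorded in the
#'   `normalization` attribute.
#' @export
normalize_profile <- function(profile, factors = NULL, per_section = TRUE) {
  if (is.null(factors)) {
    factors <- normalization_factors(profile, per_section = per_section)
  }
  key <- if (length(unique(factors$section)) == 1L &&
             factors$section[1] == "global") {
    rep("global", nrow(profile))
  } else profile$section
  f <- factors$factor[match(key, factors$section)]
  out <- profile
  out$reactivity <- profile$reactivity / f
  new_profile(out, treatment = attr(profile, "treatment"),
              normalization = factors, clamped = attr(profile, "clamped"))
}

#' Subtract the control profile from a treated profile
#'
#' Per-position difference; negative differences are clamped to zero (the
#' read-out measures degradation, which cannot be negative) and the clamp
#' count is recorded in the `clamped` attribute. Missing values propagate.
#'
#' @param treated,control Reactivity profiles on the same construct and
#'   section map.
#' @return A reactivity profile of differences.
#' @export
subtract_control <- function(treated, control) {
  if (nrow(treated) != nrow(control)) {
    abort("treated and control profiles differ in length",
          class = "mprtseq_input_error")
  }
  d <- treated$reactivity - control$reactivity
  n_clamped <- sum(d < 0, na.rm = TRUE)
  if (n_clamped > 0) {
    inform(sprintf("subtract_control: clamped %d negative value(s) to 0",
                   n_clamped))
  }
  d <- pmax(d, 0)
  out <- treated
  out$reactivity <- d
  new_profile(out, treatment = attr(treated, "treatment"),
              normalization = attr(treated, "normalization"),
              clamped = n_clamped)
}

#' Mean reactivity of a profile
#'
#' Arithmetic mean over non-missing positions.
#'
#' @param profile A reactivity profile (or any tibble with a `reactivity`
#'   column).
#' @return A scalar.
#' @export
mean_reactivity <- function(profile) {
  v <- profile$reactivity
  if (all(is.na(v))) abort("profile has no non-missing values",
                           class = "mprtseq_input_error")
  mean(v, na.rm = TRUE)
}

#' Write a reactivity profile to TSV
#'
#' Columns: position, base (if present), reactivity, section, treatment.
#'
#' @param profile A reactivity profile.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  out <- as_tibble(profile)
  out$treatment <- attr(profile, "treatment") %||% "unknown"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a reactivity profile written by [write_profile()]
#'
#' @param path TSV path.
#' @return A reactivity profile.
#' @export
read_profile <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols())
  treatment <- if ("treatment" %in% names(tb)) tb$treatment[1] else "unknown"
  tb$treatment <- NULL
  new_profile(tb, treatment = treatment)
}

#' Read / write a per-primer peak table (CSV)
#'
#' Two columns: `cdna_length`, `intensity`.
#'
#' @param path CSV path.
#' @return `read_peak_table()` returns a tibble.
#' @export
read_peak_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cdna_length = readr::col_integer(),
    intensity = readr::col_double()
  ))
}

#' @param peak_table A peak table.
#' @rdname read_peak_table
#' @export
write_peak_table <- function(peak_table, path) {
  readr::write_csv(as_tibble(peak_table)[, c("cdna_length", "intensity")], path)
  invisible(path)
}
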