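#' Describe a per-nucleotide cleavage model
#'
#' Phosphodiester backbone cleavage is modeled as a per-molecule Poisson
#' process whose sites are drawn proportional to a per-nucleotide propensity.
#' The propensity at position *i* is the product of a base-identity weight,
#' a structure-context weight for the structural element at *i*, and a
#' planted-hotspot multiplier when *i* falls inside a planted interval.
#'
#' Defaults encode the two regularities degradation read-outs show:
#' cleavage favors C, then G, then A and U roughly equally
#' (`base_weights = c(A = 1.2, C = 4, G = 2, U = 1)`), and base-paired
#' backbone is protected relative to unpaired backbone (paired elements get
#' `context_weights` 0.35, loops/exterior 1).
#'
#' @param base_weights Named nonnegative multipliers for `A`, `C`, `G`, `U`.
#' @param context_weights Named nonnegative multipliers per structural
#'   element label (see [classify_elements()]); unnamed elements default
#'   to 1.
#' @param planted_hotspots Data frame with columns `start`, `end`,
#'   `multiplier` (or `NULL`).
#' @param per_event_rate Expected cleavages per molecule per stress-dose
#'   unit (per freeze-thaw cycle, or per hour at 37 degrees C).
#' @return An object of class `cleavage_model`.
#' @export
cleavage_model <- function(base_weights = c(A = 1.2, C = 4, G = 2, U = 1),
                           context_weights = c(stem_5prime = 0.35,
                                               stem_3prime = 0.35,
                                               hairpin_loop = 1,
                                               bulge = 1,
                                               internal_loop = 1,
                                               multiloop = 1,
                                               exterior = 1),
                           planted_hotspots = NULL,
                           per_event_rate = 0.008) {
  stopifnot(all(c("A", "C", "G", "U") %in% names(base_weights)))
  if (any(base_weights < 0) || any(context_weights < 0)) {
    abort("all multipliers must be nonnegative")
  }
  if (per_event_rate < 0) abort("per_event_rate must be nonnegative")
  if (!is.null(planted_hotspots)) {
    planted_hotspots <- as_tibble(planted_hotspots)
    stopifnot(all(c("start", "end", "multiplier") %in% names(planted_hotspots)))
  }
  structure(
    list(base_weights = base_weights,
         context_weights = context_weights,
         planted_hotspots = planted_hotspots,
         per_event_rate = per_event_rate),
    class = "cleavage_model"
  )
}

#' Describe a stress dose
#'
#' @param regime `"freeze_thaw"` or `"heat_37C"`.
#' @param amount Number of freeze-thaw cycles, or hours at 37 degrees C
#'   (nonnegative).
#' @return An object of class `stress_dose`.
#' @export
stress_dose <- function(regime = c("freeze_thaw", "heat_37C"), amount = 0) {
  regime <- match.arg(regime)
  if (amount < 0) abort("dose amount must be nonnegative")
  structure(list(regime = regime, amount = amount), class = "stress_dose")
}

#' Per-nucleotide cleavage propensity
#'
#' Deterministic product of base, context and planted-hotspot multipliers.
#'
#' @param construct An [mrna_construct()].
#' @param structure A [secondary_structure()] of the same length, or `NULL`
#'   for an unstructured template (all positions treated as exterior).
#' @param model A [cleavage_model()].
#' @return Numeric vector of length `construct$length`.
#' @export
cleavage_propensity <- function(construct, structure = NULL,
                                model = cleavage_model()) {
  stopifnot(inherits(construct, "mrna_construct"),
            inherits(model, "cleavage_model"))
  bases <- strsplit(construct$sequence, "")[[1]]
  prop <- unname(model$base_weights[bases])
  if (!is.null(structure)) {
    if (structure_length(structure) != construct$length) {
      abort("structure length does not match construct length")
    }
    labels <- classify_elements(structure)$element
    cw <- model$context_weights[labels]
    cw[is.na(cw)] <- 1
    prop <- prop * unname(cw)
  }
  hs <- model$planted_hotspots
  if (!is.null(hs) && nrow(hs) > 0) {
    for (i in seq_len(nrow(hs))) {
      idx <- hs$start[i]:hs$end[i]
      prop[idx] <- prop[idx] * hs$multiplier[i]
    }
  }
  prop
}

#' Simulate a stressed fragment population
#'
#' Each of `n_molecules` template copies receives a Poisson number of chain
#' breaks with mean `per_event_rate * amount`; break sites are drawn (with
#' replacement, then de-duplicated per molecule) proportional to the
#' propensity vector. A break at site *p* severs the backbone 5' of
#' nucleotide *p*, producing fragments `(1, p-1)` and `(p, L)`; site 1 is
#' never cut. A zero dose returns only full-length molecules.
#'
#' @param propensity Per-nucleotide propensity (from
#'   [cleavage_propensity()]).
#' @param dose A [stress_dose()].
#' @param n_molecules Number of template molecules to simulate.
#' @param model A [cleavage_model()] (supplies `per_event_rate`).
#' @param seed Integer seed; the simulation is reproducible for a fixed
#'   seed and leaves the global RNG untouched.
#' @return A tibble of class `fragment_population` with columns `molecule`,
#'   `start`, `end`; attributes `n_molecules`, `template_length`, `seed`,
#'   `dose`.
#' @export
simulate_fragments <- function(propensity, dose, n_molecules,
                               model = cleavage_model(), seed = 1L) {
  stopifnot(inherits(dose, "stress_dose"), n_molecules >= 1)
  L <- length(propensity)
  lambda <- model$per_event_rate * dose$amount
  w <- propensity
  w[1] <- 0  # no bond 5' of the first nucleotide
  if (lambda > 0 && sum(w) <= 0) {
    abort("all-zero cleavage propensity with a positive event rate",
          class = "mprtseq_degenerate_model")
  }
  frags <- withr::with_seed(seed, {
    ncuts <- rpois(n_molecules, lambda)
    total <- sum(ncuts)
    sites <- if (total > 0) {
      sample.int(L, total, replace = TRUE, prob = w)
    } else integer(0)
    mol_of <- rep.int(seq_len(n_molecules), ncuts)
    cut_list <- split(sites, factor(mol_of, levels = seq_len(n_molecules)))
    starts <- vector("list", n_molecules)
    for (m in seq_len(n_molecules)) {
      cuts <- sort(unique(cut_list[[m]]))
      starts[[m]] <- c(1L, cuts)
    }
    ns <- lengths(starts)
    st <- unlist(starts, use.names = FALSE)
    en <- unlist(lapply(starts, function(s) c(s[-1] - 1L, L)),
                 use.names = FALSE)
    tibble(molecule = rep.int(seq_len(n_molecules), ns),
           start = as.integer(st), end = as.integer(en))
  })
  structure(frags,
            n_molecules = as.integer(n_molecules),
            template_length = as.integer(L),
            seed = as.integer(seed),
            dose = dose,
            class = c("fragment_population", class(frags)))
}

#' Simulate per-primer RT-stop peak tables
#'
#' Reverse transcription from each primer is ideal: any fragment that
#' contains a primer's full pairing site yields a cDNA extending from
#' `pairing_start - 1` down to the fragment's 5' end, i.e. a cDNA of length
#' `pairing_start - fragment_start`. Stop-position counts are accumulated
#' per cDNA length, optional Gaussian noise is added, and negative
#' intensities are clamped to zero.
#'
#' @param fragments A [simulate_fragments()] population.
#' @param primers An [rt_primer_panel()].
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (0 for a noise-free read-out).
#' @param seed Integer seed for the noise draw.
#' @return Named list (one per primer) of tibbles of class `peak_table`
#'   with columns `cdna_length`, `intensity`; attribute `primer` carries
#'   the primer row.
#' @export
simulate_rt_traces <- function(fragments, primers, noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  primers <- rt_primer_panel(primers)
  out <- withr::with_seed(seed, {
    lapply(seq_len(nrow(primers)), function(i) {
      ps <- primers$pairing_start[i]
      pe <- primers$pairing_end[i]
      hit <- fragments$start <= ps & fragments$end >= pe
      k <- ps - fragments$start[hit]
      k <- k[k >= 1L]
      tab <- tibble(cdna_length = as.integer(names(table(k))) %||% integer(0),
                    intensity = as.numeric(table(k)))
      if (nrow(tab) > 0 && noise_sd > 0) {
        tab$intensity <- pmax(0, tab$intensity + rnorm(nrow(tab), 0, noise_sd))
      }
      structure(tab, primer = primers[i, ],
                class = c("peak_table", class(tab)))
    })
  })
  setNames(out, primers$name)
}

#' Simulate a capillary electropherogram from a fragment population
#'
#' The mass-weighted fragment-length histogram (each fragment contributes
#' its length in nucleotides, so signal tracks stained mass) is convolved
#' with a Gaussian sizing kernel and reported on a size axis in nt.
#'
#' @param fragments A [simulate_fragments()] population.
#' @param sizing_sd Gaussian sizing spread in nt (> 0).
#' @param grid_step Size-axis step in nt.
#' @return An [electropherogram()] on a `size_nt` axis.
#' @export
simulate_electropherogram <- function(fragments, sizing_sd = 25,
                                      grid_step = 2) {
  if (nrow(fragments) == 0L) {
    abort("empty fragment population", class = "mprtseq_input_error")
  }
  stopifnot(sizing_sd > 0)
  len <- fragments$end - fragments$start + 1L
  L <- attr(fragments, "template_length") %||% max(len)
  axis <- seq(1, L + 6 * sizing_sd, by = grid_step)
  mass <- tapply(as.numeric(len), len, sum)  # mass-weighted histogram
  sizes <- as.numeric(names(mass))
  signal <- rep(0, length(axis))
  for (j in seq_along(sizes)) {
    signal <- signal + mass[[j]] * dnorm(axis, sizes[j], sizing_sd)
  }
  electropherogram(tibble(size_nt = axis, signal = signal),
                   axis_kind = "size_nt",
                   sample_name = sprintf("simulated (n=%d molecules)",
                                         attr(fragments, "n_molecules") %||% NA))
}
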