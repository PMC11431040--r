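#' The bundled GFP-Luc-style reference construct
#'
#' A deterministic 2896-nt synthetic construct used as the package's
#' reference fixture. Its element coordinates and RT primer panel mirror a
#' dual-antigen (luciferase + GFP) reporter mRNA: 5' UTR 1-52 (Kozak 47-52),
#' Luc ORF 53-1702, linker 1703-1768, GFP ORF 1769-2485, stop codons
#' 2486-2491, 3' UTR 2492-2786 and a 110-nt poly(A) tail 2787-2896. The
#' four degradation-sensitive sequence motifs characteristic of this
#' construct (GCUUCAGCC ending at 1988, CUCGCCGACC ending at 2312, UUCGU at
#' 2438-2442 and UUGGU at 2750-2754) are planted at their published-style
#' loci; the remaining sequence is drawn once from a fixed internal seed so
#' the fixture is identical across machines. The sequence is synthetic: only
#' its coordinates and motifs are meaningful, not its codons.
#'
#' @return An [mrna_construct()] of length 2896.
#' @export
#' @examples
#' ref <- reference_construct()
#' element_at(ref, 1986)
reference_construct <- function() {
  L <- 2896L
  polya_start <- 2787L
  seq <- withr::with_seed(120424, {
    # background composition loosely GC-balanced
    sample(c("A", "C", "G", "U"), L, replace = TRUE,
           prob = c(0.24, 0.27, 0.27, 0.22))
  })
  plant <- function(seq, motif, end_pos) {
    m <- strsplit(motif, "")[[1]]
    start_pos <- end_pos - length(m) + 1L
    seq[start_pos:end_pos] <- m
    seq
  }
  seq <- plant(seq, "GCUUCAGCC", 1988L)   # high GCC at 1986-1988
  seq <- plant(seq, "CUCGCCGACC", 2312L)  # high CGACC at 2308-2312
  seq <- plant(seq, "UUCGU", 2442L)       # high UUC at 2438-2440
  seq <- plant(seq, "UUGGU", 2754L)       # high UUGG at 2750-2753
  seq[polya_start:L] <- "A"
  mrna_construct("reference_GFP-Luc_synthetic",
                 paste(seq, collapse = ""),
                 reference_elements())
}

#' Reference element annotation
#'
#' Element coordinates of the reference construct (1-based inclusive). The
#' Kozak box overlaps the 3' end of the 5' UTR and is listed separately in
#' `kozak`, not in the tiling element table.
#'
#' @return A tibble with columns `label`, `start`, `end`.
#' @export
reference_elements <- function() {
  tibble(
    label = c("5' UTR", "Luc", "linker", "GFP", "stop codons", "3' UTR",
              "poly(A)"),
    start = c(1L, 53L, 1703L, 1769L, 2486L, 2492L, 2787L),
    end   = c(52L, 1702L, 1768L, 2485L, 2491L, 2786L, 2896L)
  )
}

#' Reference RT primer panel
#'
#' The six 5'-FAM-labeled reverse-transcription primers tiling the reference
#' construct, each reading the roughly 500-nt section 5' of its pairing
#' site.
#'
#' @return An [rt_primer_panel()] of six primers.
#' @export
reference_primers <- function() {
  rt_primer_panel(tibble(
    name = paste0("RT", 1:6),
    pairing_start = c(554L, 1036L, 1561L, 2065L, 2493L, 2771L),
    pairing_end   = c(573L, 1053L, 1578L, 2082L, 2510L, 2788L),
    labeled_5prime = TRUE
  ))
}

#' Reference degradation-sensitive regions
#'
#' The four regions of the reference construct with high degradation
#' reactivity under both stress regimes: the GCC at 1986-1988, the CGACC at
#' 2308-2312, the UUC run at 2438-2440 and the UUGG at 2750-2753.
#'
#' @return A tibble with columns `region`, `start`, `end`.
#' @export
reference_hotspot_regions <- function() {
  tibble(
    region = c("GCC_1986", "CGACC_2308", "UUC_2438", "UUGG_2750"),
    start = c(1986L, 2308L, 2438L, 2750L),
    end   = c(1988L, 2312L, 2440L, 2753L)
  )
}

#' Reference baseline parameters per stress regime
#'
#' The rescaled-average baseline parameters for the two stress regimes of
#' the reference study conditions: total average reactivity `A` of 3.5 with
#' rescale factor `q` of 1e-6 for freeze-thaw cycling, and `A` of 8.8 with
#' `q` of 3.5e-4 for 37 degree-C incubation.
#'
#' @return A named list of two [degradation_baseline()] objects,
#'   `freeze_thaw` and `heat_37C`.
#' @export
reference_baselines <- function() {
  list(
    freeze_thaw = degradation_baseline(A = 3.5, q = 0.000001,
                                       regime = "freeze_thaw"),
    heat_37C = degradation_baseline(A = 8.8, q = 0.00035,
                                    regime = "heat_37C")
  )
}
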