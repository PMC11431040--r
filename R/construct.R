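#' Build an annotated mRNA construct
#'
#' An `mrna_construct` couples an RNA sequence with an ordered table of
#' functional elements (UTRs, ORFs, linker, stop codons, poly(A) tail) in
#' 1-based inclusive coordinates, the numbering used throughout the package.
#'
#' Non-poly(A) elements must tile positions `1 .. polyA_start - 1` without
#' gaps or overlaps; when no poly(A) element is present they must tile the
#' whole sequence. The sequence alphabet is restricted to `A`, `C`, `G`, `U`.
#'
#' @param name Construct name.
#' @param sequence RNA sequence string over `{A,C,G,U}`. `T` is accepted and
#'   transliterated to `U` with a warning.
#' @param elements Data frame with columns `label`, `start`, `end`
#'   (1-based inclusive).
#' @return An object of class `mrna_construct`: a list with `name`,
#'   `sequence` (character scalar), `length`, and `elements` (tibble).
#' @export
#' @examples
#' mrna_construct("toy", "AUGCUUAAA",
#'                data.frame(label = c("head", "tail"),
#'                           start = c(1, 5), end = c(4, 9)))
mrna_construct <- function(name, sequence, elements) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("T", sequence, fixed = TRUE)) {
    warn("sequence contains T; transliterating to U")
    sequence <- gsub("T", "U", sequence, fixed = TRUE)
  }
  if (grepl("[^ACGU]", sequence)) {
    abort(paste0("invalid characters in sequence: ",
                 paste(unique(strsplit(gsub("[ACGU]", "", sequence), "")[[1]]),
                       collapse = ", ")))
  }
  L <- nchar(sequence)
  elements <- as_tibble(elements)
  req <- c("label", "start", "end")
  if (!all(req %in% names(elements))) {
    abort("elements must have columns label, start, end")
  }
  elements <- elements |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$start)
  validate_elements(elements, L)
  structure(
    list(name = name, sequence = sequence, length = L, elements = elements),
    class = "mrna_construct"
  )
}

validate_elements <- function(elements, L) {
  if (any(elements$start < 1L | elements$end > L | elements$start > elements$end)) {
    abort("element interval out of range: intervals must satisfy 1 <= start <= end <= length",
          class = "mprtseq_bounds_error")
  }
  polya <- grepl("poly", elements$label, ignore.case = TRUE) &
    grepl("a", elements$label, ignore.case = TRUE)
  body <- elements[!polya, , drop = FALSE]
  limit <- if (any(polya)) min(elements$start[polya]) - 1L else L
  if (nrow(body) > 0) {
    covered <- body |> arrange(.data$start)
    expected_start <- 1L
    for (i in seq_len(nrow(covered))) {
      if (covered$start[i] != expected_start) {
        abort(sprintf(
          "non-poly(A) elements must tile 1..%d without gaps or overlaps (problem at '%s', start %d, expected %d)",
          limit, covered$label[i], covered$start[i], expected_start),
          class = "mprtseq_annotation_error")
      }
      expected_start <- covered$end[i] + 1L
    }
    if (expected_start != limit + 1L) {
      abort(sprintf("non-poly(A) elements end at %d but must reach %d",
                    expected_start - 1L, limit),
            class = "mprtseq_annotation_error")
    }
  }
  invisible(elements)
}

#' @export
print.mrna_construct <- function(x, ...) {
  cat(sprintf("<mrna_construct> %s: %d nt, %d elements\n",
              x$name, x$length, nrow(x$elements)))
  print(x$elements, n = nrow(x$elements))
  invisible(x)
}

#' Load a construct from a FASTA file and an annotation table
#'
#' Reads a single-record FASTA (DNA records are transliterated to RNA) and
#' attaches the element annotation.
#'
#' @param fasta_path Path to a FASTA file containing exactly one record.
#' @param annotation Either a data frame with columns `label`, `start`, `end`
#'   or a path to a TSV file with those columns.
#' @return An [mrna_construct()].
#' @export
load_construct <- function(fasta_path, annotation) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) != 1L) {
    abort(sprintf("FASTA must contain exactly one record, found %d", length(seqs)))
  }
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read_annotation(annotation)
  }
  mrna_construct(names(seqs)[1], as.character(seqs[[1]]), annotation)
}

#' Read / write an element annotation table
#'
#' Plain TSV with header columns `label`, `start`, `end`.
#'
#' @param path File path.
#' @return `read_annotation()` returns a tibble; `write_annotation()` returns
#'   `path` invisibly.
#' @export
read_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    label = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer()
  ))
}

#' @param elements Data frame with columns `label`, `start`, `end`.
#' @rdname read_annotation
#' @export
write_annotation <- function(elements, path) {
  readr::write_tsv(as_tibble(elements)[, c("label", "start", "end")], path)
  invisible(path)
}

#' Look up which element a position falls in
#'
#' @param construct An [mrna_construct()].
#' @param position 1-based position(s).
#' @return Character vector of element labels.
#' @export
element_at <- function(construct, position) {
  stopifnot(inherits(construct, "mrna_construct"))
  if (any(position < 1L | position > construct$length)) {
    abort(sprintf("position out of range 1..%d", construct$length),
          class = "mprtseq_bounds_error")
  }
  el <- construct$elements
  vapply(position, function(p) {
    hit <- which(el$start <= p & el$end >= p)
    if (length(hit) == 0L) NA_character_ else el$label[hit[1]]
  }, character(1))
}

#' Define an RT primer panel
#'
#' Validates a table of reverse-transcription primers. Each primer anneals on
#' `pairing_start..pairing_end` (1-based inclusive, on the mRNA) and, when
#' 5'-FAM labeled, its cDNA lengths are read out by capillary electrophoresis.
#'
#' @param primers Data frame with columns `name`, `pairing_start`,
#'   `pairing_end` and optionally `labeled_5prime` (default `TRUE`).
#' @return A tibble of class `rt_primer_panel`, sorted by `pairing_start`.
#' @export
rt_primer_panel <- function(primers) {
  primers <- as_tibble(primers)
  req <- c("name", "pairing_start", "pairing_end")
  if (!all(req %in% names(primers))) {
    abort("primers must have columns name, pairing_start, pairing_end")
  }
  if (!"labeled_5prime" %in% names(primers)) primers$labeled_5prime <- TRUE
  primers <- primers |>
    mutate(pairing_start = as.integer(.data$pairing_start),
           pairing_end = as.integer(.data$pairing_end)) |>
    arrange(.data$pairing_start)
  if (any(primers$pairing_start >= primers$pairing_end)) {
    abort("each primer must satisfy pairing_start < pairing_end")
  }
  if (nrow(primers) > 1) {
    ok <- head(primers$pairing_end, -1) < tail(primers$pairing_start, -1)
    if (!all(ok)) abort("primer pairing intervals must be mutually disjoint")
  }
  class(primers) <- c("rt_primer_panel", class(primers))
  primers
}

#' Read / write an RT primer table
#'
#' TSV with columns `name`, `pairing_start`, `pairing_end` and optional
#' `labeled_5prime`.
#'
#' @param path File path.
#' @return `read_primers()` returns an [rt_primer_panel()].
#' @export
read_primers <- function(path) {
  rt_primer_panel(readr::read_tsv(path, col_types = readr::cols()))
}

#' @param primers An [rt_primer_panel()] or compatible data frame.
#' @rdname read_primers
#' @export
write_primers <- function(primers, path) {
  readr::write_tsv(as_tibble(primers), path)
  invisible(path)
}

#' Partition the template into per-primer read-out sections
#'
#' Each primer reads RT stops 5' of its pairing site, so the template is
#' split between adjacent pairing positions: the 5'-most primer owns
#' `1 .. pairing_start - 1`, and primer *i* owns
#' `pairing_start[i-1] .. pairing_start[i] - 1`. Positions at or 3' of the
#' last primer's pairing start (including the poly(A) tail) are read by no
#' primer and are reported in the `uncovered` attribute.
#'
#' @param primers An [rt_primer_panel()].
#' @param construct_length Template length in nt.
#' @return A tibble of class `section_map` with columns `primer`, `start`,
#'   `end`; attribute `uncovered` holds the unread interval (or `NULL`).
#' @export
build_section_map <- function(primers, construct_length) {
  if (is.null(primers) || nrow(primers) == 0L) {
    abort("at least one primer is required", class = "mprtseq_config_error")
  }
  primers <- rt_primer_panel(primers)
  starts <- c(1L, head(primers$pairing_start, -1))
  ends <- primers$pairing_start - 1L
  sm <- tibble(primer = primers$name, start = starts, end = ends)
  last <- tail(primers$pairing_start, 1)
  uncovered <- if (last <= construct_length) {
    c(last, as.integer(construct_length))
  } else NULL
  structure(sm, uncovered = uncovered,
            construct_length = as.integer(construct_length),
            class = c("section_map", class(sm)))
}

#' Which section owns a position
#'
#' @param section_map A [build_section_map()] result.
#' @param position 1-based position(s).
#' @return Character vector of owning primer names (`NA` if uncovered).
#' @export
section_at <- function(section_map, position) {
  vapply(position, function(p) {
    hit <- which(section_map$start <= p & section_map$end >= p)
    if (length(hit) == 0L) NA_character_ else section_map$primer[hit[1]]
  }, character(1))
}

#' Write a construct to FASTA
#'
#' @param construct An [mrna_construct()].
#' @param path Output path.
#' @export
write_construct_fasta <- function(construct, path) {
  x <- Biostrings::RNAStringSet(construct$sequence)
  names(x) <- construct$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
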