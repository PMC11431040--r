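#' Parse a dot-bracket secondary structure
#'
#' Stack-matches `(`/`)` into a base-pair table. Only plain brackets are
#' accepted: pseudoknot notations (`[`, `{`, letters) are rejected rather
#' than silently mis-parsed.
#'
#' @param text Dot-bracket string over `{., (, )}`.
#' @return An object of class `secondary_structure`: list with `dotbracket`
#'   and `pair` (integer vector; `pair[i] = j` if i pairs j, `NA` if
#'   unpaired).
#' @export
#' @examples
#' parse_dotbracket("((..))")
parse_dotbracket <- function(text) {
  chars <- strsplit(text, "")[[1]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0) {
    abort(sprintf("invalid character '%s' at position %d (pseudoknot brackets are not supported)",
                  chars[bad[1]], bad[1]), class = "mprtseq_parse_error")
  }
  n <- length(chars)
  pair <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        abort(sprintf("unbalanced ')' at position %d", i),
              class = "mprtseq_parse_error")
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[j] <- i
      pair[i] <- j
    }
  }
  if (length(stack) > 0L) {
    abort(sprintf("unbalanced '(' at position %d", stack[1]),
          class = "mprtseq_parse_error")
  }
  structure(list(dotbracket = text, pair = pair),
            class = "secondary_structure")
}

structure_length <- function(structure) length(structure$pair)

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d base pairs\n",
              structure_length(x), sum(!is.na(x$pair)) / 2))
  invisible(x)
}

#' Read / write Vienna dot-bracket files
#'
#' A Vienna file holds an optional `>name` header, a sequence line, and a
#' structure line. `read_vienna()` returns the structure with the sequence
#' attached; `write_vienna()` writes one.
#'
#' @param path File path.
#' @return `read_vienna()` returns a `secondary_structure` with attributes
#'   `sequence` and `name`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- NULL
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 2) abort("Vienna file needs a sequence and a structure line")
  seq <- trimws(lines[1])
  db <- strsplit(trimws(lines[2]), "\\s+")[[1]][1]  # drop trailing energy
  if (nchar(seq) != nchar(db)) {
    abort("sequence and structure lines differ in length",
          class = "mprtseq_parse_error")
  }
  s <- parse_dotbracket(db)
  attr(s, "sequence") <- seq
  attr(s, "name") <- name
  s
}

#' @param structure A `secondary_structure`.
#' @param sequence Sequence line (defaults to the attached sequence, else
#'   `N` runs).
#' @param name Optional record name.
#' @rdname read_vienna
#' @export
write_vienna <- function(structure, path, sequence = NULL, name = NULL) {
  sequence <- sequence %||% attr(structure, "sequence") %||%
    strrep("N", structure_length(structure))
  name <- name %||% attr(structure, "name")
  lines <- c(if (!is.null(name)) paste0(">", name),
             sequence, structure$dotbracket)
  writeLines(lines, path)
  invisible(path)
}

#' Export a connectivity table (.ct)
#'
#' @param structure A `secondary_structure`.
#' @param path Output path.
#' @param sequence Sequence (defaults to attached sequence or `N`s).
#' @param name Record name for the header line.
#' @export
write_ct <- function(structure, path, sequence = NULL, name = "structure") {
  n <- structure_length(structure)
  sequence <- sequence %||% attr(structure, "sequence") %||% strrep("N", n)
  bases <- strsplit(sequence, "")[[1]]
  pair <- structure$pair
  pair[is.na(pair)] <- 0L
  lines <- c(sprintf("%d %s", n, name),
             sprintf("%d %s %d %d %d %d",
                     1:n, bases, 0:(n - 1), c(2:n, 0), pair, 1:n))
  writeLines(lines, path)
  invisible(path)
}

#' Classify every nucleotide's structural element
#'
#' Paired positions are labeled `stem_5prime` when they pair downstream
#' (i < j) and `stem_3prime` otherwise. Unpaired positions are labeled by
#' the loop that directly contains them, identified by the loop's number of
#' closing pairs: `hairpin_loop` (one closing pair, no enclosed helices),
#' `bulge` (two closing pairs, unpaired bases on exactly one strand),
#' `internal_loop` (two closing pairs, unpaired on both strands),
#' `multiloop` (three or more closing pairs), and `exterior` for positions
#' enclosed by no pair.
#'
#' @param structure A `secondary_structure` (or dot-bracket string).
#' @return A tibble with columns `position`, `element`.
#' @export
classify_elements <- function(structure) {
  if (is.character(structure)) structure <- parse_dotbracket(structure)
  pair <- structure$pair
  n <- length(pair)
  element <- character(n)
  element[!is.na(pair) & seq_len(n) < pair] <- "stem_5prime"
  element[!is.na(pair) & seq_len(n) > pair] <- "stem_3prime"

  # one linear pass: for each unpaired position, the directly enclosing pair
  enclosing <- rep(NA_integer_, n)  # 5' index of the enclosing pair
  stack <- integer(0)
  chars <- strsplit(structure$dotbracket, "")[[1]]
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      stack <- stack[-length(stack)]
    } else if (length(stack) > 0) {
      enclosing[i] <- stack[length(stack)]
    }
  }
  unpaired <- which(is.na(pair))
  ext <- unpaired[is.na(enclosing[unpaired])]
  element[ext] <- "exterior"
  loops <- split(unpaired[!is.na(enclosing[unpaired])],
                 enclosing[unpaired[!is.na(enclosing[unpaired])]])
  for (key in names(loops)) {
    i <- as.integer(key)
    lab <- loop_label(pair, i)
    element[loops[[key]]] <- lab
  }
  tibble(position = seq_len(n), element = element)
}

# classify the loop closed by pair (i, pair[i]) by walking its interior
loop_label <- function(pair, i) {
  j <- pair[i]
  branches <- 0L
  side5 <- 0L  # unpaired before the first branch / after i
  side3 <- 0L  # unpaired after the last branch / before j
  unpaired_between <- FALSE
  k <- i + 1L
  seen_branch <- FALSE
  run_since_branch <- 0L
  while (k < j) {
    if (!is.na(pair[k])) {
      branches <- branches + 1L
      if (seen_branch && run_since_branch > 0L) unpaired_between <- TRUE
      seen_branch <- TRUE
      run_since_branch <- 0L
      k <- pair[k] + 1L
    } else {
      if (!seen_branch) side5 <- side5 + 1L else run_since_branch <- run_since_branch + 1L
      k <- k + 1L
    }
  }
  side3 <- run_since_branch
  if (branches == 0L) return("hairpin_loop")
  if (branches >= 2L) return("multiloop")
  # one branch: interior-loop family
  if ((side5 > 0L) && (side3 > 0L)) "internal_loop" else "bulge"
}

#' Annotate a hotspot with secondary-structure motif context
#'
#' Answers the three questions used to characterize degradation-sensitive
#' sites: does the hotspot sit on the 5' strand of a helix, does the helix
#' stack it belongs to terminate in an apical (hairpin) loop, and is that
#' stack interrupted by a bulge or internal loop between the hotspot and
#' the apical loop (or within the hotspot span)?
#'
#' `on_5prime_stem_side` is the majority vote over the hotspot's paired
#' positions. The helix stack is walked inward from the hotspot's innermost
#' base pair, crossing bulges and internal loops (each crossing recorded)
#' until a hairpin loop (apical) or a multiloop ends the walk.
#'
#' @param hotspot A single hotspot: any list/row with `start` and `end`.
#' @param structure A `secondary_structure`.
#' @return A one-row tibble of class `motif_summary`: `on_5prime_stem_side`,
#'   `has_apical_loop`, `has_mid_stem_bulge`, `helix_start`, `helix_end`
#'   (enclosing hairpin span, `NA` if none), `dist_to_loop`,
#'   `dist_to_bulge` (nt from the hotspot's inner edge; `NA` when absent).
#' @export
annotate_hotspot_structure <- function(hotspot, structure) {
  n <- structure_length(structure)
  start <- as.integer(hotspot$start[1] %||% hotspot[["start"]])
  end <- as.integer(hotspot$end[1] %||% hotspot[["end"]])
  if (is.na(start) || is.na(end) || start < 1 || end > n) {
    abort("hotspot span outside structure", class = "mprtseq_bounds_error")
  }
  pair <- structure$pair
  labels <- classify_elements(structure)$element
  span <- start:end
  paired <- span[!is.na(pair[span])]

  on5 <- length(paired) > 0 &&
    sum(labels[paired] == "stem_5prime") > length(paired) / 2

  has_apical <- FALSE
  has_bulge <- FALSE
  helix_start <- NA_integer_
  helix_end <- NA_integer_
  dist_loop <- NA_integer_
  dist_bulge <- NA_integer_

  # bulge/internal loop inside the hotspot span itself
  if (any(labels[span] %in% c("bulge", "internal_loop"))) {
    has_bulge <- TRUE
    dist_bulge <- 0L
  }

  if (length(paired) > 0) {
    # innermost hotspot pair: smallest enclosed region
    widths <- abs(pair[paired] - paired)
    p5 <- paired[which.min(widths)]
    i <- min(p5, pair[p5]); j <- max(p5, pair[p5])
    inner_edge <- if (on5) max(paired) else min(paired)
    repeat {
      lab <- inner_loop_of(pair, i, j)
      if (lab$kind == "hairpin") {
        has_apical <- TRUE
        helix_start <- i; helix_end <- j
        dist_loop <- min(abs(lab$loop_start - inner_edge),
                         abs(lab$loop_end - inner_edge))
        break
      } else if (lab$kind == "one_branch") {
        if (lab$interrupted) {
          has_bulge <- TRUE
          d <- min(abs(lab$gap_positions - inner_edge))
          dist_bulge <- if (is.na(dist_bulge)) d else min(dist_bulge, d)
        }
        i <- lab$child_i; j <- lab$child_j
      } else {  # multiloop or stacked ambiguity ends the walk
        break
      }
    }
  }
  out <- tibble(on_5prime_stem_side = on5,
                has_apical_loop = has_apical,
                has_mid_stem_bulge = has_bulge,
                helix_start = helix_start,
                helix_end = helix_end,
                dist_to_loop = as.integer(dist_loop),
                dist_to_bulge = as.integer(dist_bulge))
  class(out) <- c("motif_summary", class(out))
  out
}

# inspect the loop immediately inside pair (i, j)
inner_loop_of <- function(pair, i, j) {
  k <- i + 1L
  children <- list()
  gaps <- integer(0)
  while (k < j) {
    if (!is.na(pair[k])) {
      children[[length(children) + 1L]] <- c(k, pair[k])
      k <- pair[k] + 1L
    } else {
      gaps <- c(gaps, k)
      k <- k + 1L
    }
  }
  if (length(children) == 0L) {
    return(list(kind = "hairpin",
                loop_start = i + 1L, loop_end = j - 1L))
  }
  if (length(children) == 1L) {
    return(list(kind = "one_branch",
                child_i = children[[1]][1], child_j = children[[1]][2],
                interrupted = length(gaps) > 0L,
                gap_positions = if (length(gaps)) gaps else NA_integer_))
  }
  list(kind = "multiloop")
}

#' Annotate every hotspot call with motif context
#'
#' @param calls A [find_hotspots()] table.
#' @param structure A `secondary_structure`.
#' @return `calls` with the [annotate_hotspot_structure()] columns bound on.
#' @export
annotate_hotspots <- function(calls, structure) {
  if (nrow(calls) == 0L) return(calls)
  ann <- purrr::map(seq_len(nrow(calls)), function(i) {
    annotate_hotspot_structure(calls[i, ], structure)
  }) |> dplyr::bind_rows()
  out <- dplyr::bind_cols(as_tibble(calls), ann)
  attr(out, "conditions") <- attr(calls, "conditions")
  class(out) <- c("hotspot_calls", class(tibble()))
  out
}
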