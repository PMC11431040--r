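# Independent oracles and small fixtures shared across tests.

# All balanced dot-bracket strings of exactly length n (breadth-first build).
enumerate_dotbrackets <- function(n) {
  states <- list(list(s = "", open = 0L))
  for (step in seq_len(n)) {
    nxt <- list()
    for (st in states) {
      remaining <- n - step + 1L
      # '.' always allowed if the opens can still close
      if (st$open <= remaining - 1L) {
        nxt[[length(nxt) + 1L]] <- list(s = paste0(st$s, "."), open = st$open)
      }
      if (st$open + 1L <= remaining - 1L) {
        nxt[[length(nxt) + 1L]] <- list(s = paste0(st$s, "("),
                                        open = st$open + 1L)
      }
      if (st$open > 0L) {
        nxt[[length(nxt) + 1L]] <- list(s = paste0(st$s, ")"),
                                        open = st$open - 1L)
      }
    }
    states <- nxt
  }
  vapply(states[vapply(states, function(st) st$open == 0L, logical(1))],
         function(st) st$s, character(1))
}

# Brute-force loop-decomposition oracle, independent of classify_elements():
# for every unpaired position find the minimal enclosing pair by scanning all
# pairs, then enumerate that loop's interior to count branches and sides.
oracle_elements <- function(db) {
  chars <- strsplit(db, "")[[1]]
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") {
      pt[i] <- stack[length(stack)]
      pt[stack[length(stack)]] <- i
      stack <- stack[-length(stack)]
    }
  }
  pairs5 <- which(!is.na(pt) & seq_len(n) < pt)
  out <- character(n)
  for (k in seq_len(n)) {
    if (!is.na(pt[k])) {
      out[k] <- if (k < pt[k]) "stem_5prime" else "stem_3prime"
      next
    }
    enclosing <- pairs5[pairs5 < k & pt[pairs5] > k]
    if (length(enclosing) == 0L) {
      out[k] <- "exterior"
      next
    }
    widths <- pt[enclosing] - enclosing
    i <- enclosing[which.min(widths)]
    j <- pt[i]
    # walk the loop interior of (i, j)
    t <- i + 1L
    branch_i <- integer(0)
    branch_j <- integer(0)
    unp <- integer(0)
    while (t < j) {
      if (!is.na(pt[t])) {
        branch_i <- c(branch_i, t)
        branch_j <- c(branch_j, pt[t])
        t <- pt[t] + 1L
      } else {
        unp <- c(unp, t)
        t <- t + 1L
      }
    }
    nb <- length(branch_i)
    out[k] <- if (nb == 0L) {
      "hairpin_loop"
    } else if (nb >= 2L) {
      "multiloop"
    } else {
      side5 <- any(unp < branch_i[1])
      side3 <- any(unp > branch_j[1])
      if (side5 && side3) "internal_loop" else "bulge"
    }
  }
  out
}

# Reverse a dot-bracket string and swap the brackets (mirror structure).
mirror_dotbracket <- function(db) {
  chars <- rev(strsplit(db, "")[[1]])
  chars <- chartr("()", ")(", paste(chars, collapse = ""))
  chars
}

# A small single-element construct with a fixed random sequence.
toy_construct <- function(L, seed = 99, name = "toy") {
  seq <- withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""))
  mrna_construct(name, seq,
                 data.frame(label = "body", start = 1L, end = L))
}

# Build a reactivity profile tibble directly (for operations that only need
# position/reactivity/section columns).
toy_profile <- function(values, section = "S1", treatment = "test") {
  prof <- tibble::tibble(position = seq_along(values),
                         reactivity = values,
                         section = section)
  class(prof) <- c("reactivity_profile", class(tibble::tibble()))
  attr(prof, "treatment") <- treatment
  prof
}

# Deterministic reference profiles with planted high reactivity at the four
# degradation-sensitive regions, one per stress regime: background at half
# the regime average, hotspots at ten times it.
reference_planted_profiles <- function() {
  ref <- reference_construct()
  regions <- reference_hotspot_regions()
  bls <- reference_baselines()
  lapply(bls, function(b) {
    v <- rep(b$A / 2, ref$length)
    for (i in seq_len(nrow(regions))) {
      v[regions$start[i]:regions$end[i]] <- 10 * b$A
    }
    toy_profile(v, treatment = b$regime)
  })
}
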