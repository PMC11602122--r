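# Independent oracles and random-case generators for the scanner tests.
# The naive matcher is written from the IUPAC definitions alone and shares
# no code with the package's Biostrings-based scan path.

oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# 15x15 lookup: do two IUPAC letters share at least one base?
oracle_match <- local({
  letters15 <- names(oracle_sets)
  m <- matrix(FALSE, 15L, 15L, dimnames = list(letters15, letters15))
  for (a in letters15) {
    for (b in letters15) {
      m[a, b] <- length(intersect(oracle_sets[[a]], oracle_sets[[b]])) > 0L
    }
  }
  m
})

# Position-by-position matcher, 1-based starts.
naive_scan <- function(seq, motif, topology = "linear") {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  m <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  L <- length(s)
  k <- length(m)
  if (k > L) return(integer(0))
  n_pos <- if (topology == "linear") L - k + 1L else L
  ok <- rep(TRUE, n_pos)
  for (i in seq_len(k)) {
    idx <- if (topology == "linear") {
      seq_len(n_pos) + i - 1L
    } else {
      ((seq_len(n_pos) - 1L + i - 1L) %% L) + 1L
    }
    ok <- ok & oracle_match[cbind(m[i], s[idx])]
  }
  which(ok)
}

# Circular count by explicit brute force over all rotations: a circular
# match starts at p iff the rotation beginning at p carries the motif as a
# prefix.
rotation_count <- function(seq, motif) {
  L <- nchar(seq)
  k <- nchar(motif)
  if (k > L) return(0L)
  m <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  hits <- 0L
  for (p in seq_len(L)) {
    rotated <- paste0(substr(seq, p, L), substr(seq, 1L, p - 1L))
    prefix <- strsplit(substr(rotated, 1L, k), "", fixed = TRUE)[[1L]]
    if (all(oracle_match[cbind(m, prefix)])) hits <- hits + 1L
  }
  hits
}

random_seq <- function(L, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random IUPAC motifs, including bipartite ones with N spacers, in the
# style of real recognition sites (mostly determinate letters).
random_motif <- function() {
  letters15 <- names(oracle_sets)
  weights <- c(rep(8, 4), rep(1, 10), 0.5)
  if (stats::runif(1) < 0.35) {
    left <- sample(letters15, sample(3:5, 1L), replace = TRUE, prob = weights)
    gap <- rep("N", sample(5:9, 1L))
    right <- sample(letters15, sample(3:5, 1L), replace = TRUE, prob = weights)
    paste(c(left, gap, right), collapse = "")
  } else {
    paste(sample(letters15, sample(4:8, 1L), replace = TRUE, prob = weights),
          collapse = "")
  }
}

rc_plain <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(toupper(seq), "", fixed = TRUE)[[1L]]]),
        collapse = "")
}

rotate_seq <- function(seq, by) {
  L <- nchar(seq)
  by <- ((by - 1L) %% L) + 1L
  paste0(substr(seq, by, L), substr(seq, 1L, by - 1L))
}

# Minimal valid assay row builder for mating tests.
make_assay <- function(colonies_T, dilution_T = 1, colonies_D = 100,
                       dilution_D = 1e6, colonies_R = 100, dilution_R = 1e6,
                       plated_volume = 1, time_h = 4, ...) {
  tibble::tibble(
    colonies_T = colonies_T, dilution_T = dilution_T,
    colonies_D = colonies_D, dilution_D = dilution_D,
    colonies_R = colonies_R, dilution_R = dilution_R,
    plated_volume = plated_volume, time_h = time_h, ...
  )
}
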