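# Restriction-modification enzyme catalog and IUPAC motif algebra.

# IUPAC nucleotide ambiguity codes mapped to the sets of bases they allow.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B",
  D = "H", H = "D", N = "N"
)

RM_TYPES <- c("I", "II", "III")

#' Validate and normalize an IUPAC motif
#'
#' Upper-cases the motif and checks that every character is one of the 15
#' IUPAC nucleotide codes (A, C, G, T, R, Y, S, W, K, M, B, D, H, V, N).
#'
#' @param motif A single character string.
#' @return The normalized (upper-case) motif.
#' @keywords internal
validate_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif) ||
      nchar(motif) == 0L) {
    stop("motif must be a single non-empty character string", call. = FALSE)
  }
  motif <- toupper(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid IUPAC character(s) '%s' in motif '%s' at position(s) %s",
      paste(unique(chars[bad]), collapse = ""), motif,
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  motif
}

#' Reverse complement of an IUPAC motif
#'
#' Applies the IUPAC complement table (A<->T, C<->G, R<->Y, K<->M, B<->V,
#' D<->H; W, S, N self-complementary) and reverses the string. Works for any
#' degenerate motif, including bipartite recognition sequences with runs of N.
#'
#' @param motif IUPAC nucleotide string (case-insensitive).
#' @return The reverse-complemented IUPAC string, upper case.
#' @examples
#' reverse_complement("GAATTC") # palindromic: "GAATTC"
#' reverse_complement("AGACC")  # "GGTCT"
#' @export
reverse_complement <- function(motif) {
  motif <- validate_motif(motif)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
}

#' Is a motif a degenerate palindrome?
#'
#' TRUE when the motif equals its own IUPAC reverse complement, e.g. GAATTC
#' or CCWGG. Palindromic recognition sites occupy the same duplex position on
#' both strands, which determines the duplex counting convention used by
#' [count_sites()].
#'
#' @inheritParams reverse_complement
#' @return Logical scalar.
#' @export
is_degenerate_palindrome <- function(motif) {
  motif <- validate_motif(motif)
  identical(reverse_complement(motif), motif)
}

#' Base-composition null model
#'
#' A zero-order, strand-symmetric base composition parameterized by GC
#' content: p(G) = p(C) = gc/2 and p(A) = p(T) = (1 - gc)/2.
#'
#' @param gc GC fraction in \[0, 1\].
#' @return An object of class `composition_model` with elements `gc` and
#'   `probs` (named base probabilities).
#' @export
composition_model <- function(gc) {
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1) {
    stop("gc must be a single number in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      gc = gc,
      probs = c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    ),
    class = "composition_model"
  )
}

#' Probability that a random position matches a degenerate motif
#'
#' Under a zero-order composition model, the match probability is the product
#' over motif positions of the summed probabilities of the bases each IUPAC
#' code allows. N positions contribute a factor of 1, so bipartite motifs
#' with N spacers are handled naturally.
#'
#' @param motif IUPAC nucleotide string.
#' @param model A [composition_model()].
#' @return Probability in \[0, 1\].
#' @examples
#' motif_probability("GAATTC", composition_model(0.5)) # 0.25^6
#' @export
motif_probability <- function(motif, model) {
  motif <- validate_motif(motif)
  stopifnot(inherits(model, "composition_model"))
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  prod(vapply(chars, function(ch) sum(model$probs[IUPAC_SETS[[ch]]]), 0))
}

#' Parse a restriction-modification enzyme table
#'
#' Reads a tab-separated table with header columns `name`, `type` and
#' `recognition` (an optional `encoded_on` column is kept as metadata).
#' Recognition sequences are validated against the IUPAC alphabet and
#' normalized to upper case; `type` must be one of I, II, III.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `name`, `rm_type`, `recognition` and
#'   (if present) `encoded_on`, one row per enzyme.
#' @export
parse_enzyme_table <- function(path) {
  if (!file.exists(path)) stop("enzyme table not found: ", path, call. = FALSE)
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", strip.white = TRUE)
  required <- c("name", "type", "recognition")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("enzyme table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0L) {
    return(tibble::tibble(name = character(), rm_type = character(),
                          recognition = character()))
  }
  for (i in seq_len(nrow(tbl))) {
    row_label <- sprintf("line %d (enzyme '%s')", i + 1L, tbl$name[i])
    if (is.na(tbl$name[i]) || tbl$name[i] == "" ||
        is.na(tbl$recognition[i]) || tbl$recognition[i] == "") {
      stop("malformed enzyme table row at ", row_label, call. = FALSE)
    }
    if (!tbl$type[i] %in% RM_TYPES) {
      stop(sprintf("unknown RM type code '%s' at %s (expected I, II or III)",
                   tbl$type[i], row_label), call. = FALSE)
    }
    tbl$recognition[i] <- tryCatch(
      validate_motif(tbl$recognition[i]),
      error = function(e) stop(conditionMessage(e), " at ", row_label,
                               call. = FALSE)
    )
  }
  out <- tibble::tibble(
    name = tbl$name,
    rm_type = tbl$type,
    recognition = tbl$recognition
  )
  if ("encoded_on" %in% names(tbl)) out$encoded_on <- tbl$encoded_on
  out
}

#' Default RM-system catalog
#'
#' The ten Escherichia coli RM systems studied across the package's examples:
#' four Type I (bipartite gapped sites), four Type II (short, mostly
#' palindromic sites) and two Type III (short asymmetric sites) systems.
#' Recognition sequences follow their standard REBASE definitions and are
#' shipped as data in `inst/extdata/rm_enzymes.tsv`.
#'
#' @return A tibble as returned by [parse_enzyme_table()].
#' @export
rm_enzyme_catalog <- function() {
  parse_enzyme_table(system.file("extdata", "rm_enzymes.tsv",
                                 package = "rmconj", mustWork = TRUE))
}
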