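# IUPAC nucleotide alphabet: symbol -> base-set tables and the matching
# semantics used by every motif operator in the package.

IUPAC_SETS <- list(
  G = "G", A = "A", T = "T", C = "C",
  R = c("G", "A"), Y = c("T", "C"), M = c("A", "C"), K = c("G", "T"),
  S = c("G", "C"), W = c("A", "T"),
  H = c("A", "C", "T"), B = c("G", "T", "C"), V = c("G", "C", "A"),
  D = c("G", "A", "T"),
  N = c("G", "A", "T", "C")
)

IUPAC_SYMBOLS <- names(IUPAC_SETS)
BASE_SYMBOLS <- c("A", "C", "G", "T")

#' IUPAC alphabet for motif construction
#'
#' Returns the active motif alphabet: either the full 15-symbol IUPAC
#' nucleotide code (four bases plus eleven degenerate symbols, each denoting
#' a set of bases) or the plain `{A,C,G,T}` alphabet. The restricted alphabet
#' is useful where degenerate symbols add no signal, e.g. splice-site
#' recognition, and is a first-class switch throughout the package.
#'
#' @param mode `"iupac"` for the full degenerate code, `"acgt"` for the
#'   four-base alphabet.
#' @return Character vector of the symbols usable in motifs, with class
#'   `"motif_alphabet"`.
#' @examples
#' iupac_alphabet()
#' iupac_alphabet("acgt")
#' @export
iupac_alphabet <- function(mode = c("iupac", "acgt")) {
  mode <- match.arg(mode)
  syms <- if (mode == "iupac") IUPAC_SYMBOLS else BASE_SYMBOLS
  structure(syms, mode = mode, class = "motif_alphabet")
}

#' Expand an IUPAC symbol into its base set
#'
#' @param symbol Single character, a symbol of the active alphabet.
#' @param alphabet A [iupac_alphabet()] object; symbols outside it are
#'   rejected, so the `"acgt"` alphabet refuses degenerate symbols.
#' @return Character vector of concrete bases the symbol stands for.
#' @examples
#' expand_iupac("R")  # G or A (purine)
#' expand_iupac("N")  # any base
#' @export
expand_iupac <- function(symbol, alphabet = iupac_alphabet()) {
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L)
    stop("`symbol` must be a single character", call. = FALSE)
  if (!symbol %in% alphabet)
    stop("unknown symbol for the active alphabet: '", symbol, "'",
         call. = FALSE)
  IUPAC_SETS[[symbol]]
}

# Integer encoding of sequence characters. Concrete bases get codes 1..4;
# every other character (IUPAC-ambiguous input bases when allowed) keeps its
# own code so that coverage can be decided symbol-by-symbol.
SEQ_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L,
               R = 5L, Y = 6L, M = 7L, K = 8L, S = 9L, W = 10L,
               H = 11L, B = 12L, V = 13L, D = 14L, N = 15L)

# covers[symbol, code]: does motif symbol `symbol` match an input character
# with integer code `code`? A concrete base matches iff it is in the symbol's
# set; an ambiguous input character matches iff the motif symbol's base set
# covers (is a superset of) the input character's base set.
iupac_cover_table <- function() {
  tab <- matrix(FALSE, nrow = length(IUPAC_SYMBOLS), ncol = length(SEQ_CODES),
                dimnames = list(IUPAC_SYMBOLS, names(SEQ_CODES)))
  for (s in IUPAC_SYMBOLS) {
    for (x in names(SEQ_CODES)) {
      tab[s, x] <- all(IUPAC_SETS[[x]] %in% IUPAC_SETS[[s]])
    }
  }
  tab
}

IUPAC_COVERS <- iupac_cover_table()

# Encode sequences (character vector, all same length) as an integer matrix
# of dimension n_sequences x window_length.
encode_sequences <- function(sequences) {
  if (length(sequences) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("sequences must all have equal length; got lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(sequences), ncol = lens[1L], byrow = TRUE)
  codes <- SEQ_CODES[chars]
  bad <- is.na(codes)
  if (any(bad))
    stop("sequence contains non-IUPAC character(s): ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  matrix(unname(codes), nrow = nrow(chars), ncol = ncol(chars))
}
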