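## Domain model: modified k-mers over {A,C,G,T,M} and methylated 11-mer
## windows.  M denotes 5-methylcytosine and, in CpG context, must be followed
## by G wherever a successor position exists.

MOD_LETTERS <- c("A", "C", "G", "T", "M")

#' Modified-k-mer alphabet
#'
#' The five-letter alphabet \{A, C, G, T, M\} in which M marks a
#' 5-methylcytosine, together with the pore context length `k`.
#'
#' @param letters Character vector of single-letter symbols (default the
#'   standard five-letter modified alphabet).
#' @param k Pore context length (number of bases in the pore at once),
#'   default 6.
#' @return An object of class `mod_alphabet`.
#' @examples
#' ab <- mod_alphabet()
#' length(enumerate_kmers(ab, k = 2))
#' @export
mod_alphabet <- function(letters = MOD_LETTERS, k = 6L) {
  if (anyDuplicated(letters) || any(nchar(letters) != 1L))
    stop("alphabet letters must be distinct single characters")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  structure(list(letters = letters, k = k), class = "mod_alphabet")
}

#' @export
print.mod_alphabet <- function(x, ...) {
  cat("alphabet {", paste(x$letters, collapse = ","), "}, k =", x$k, "\n")
  invisible(x)
}

#' Enumerate all k-mers over an alphabet
#'
#' With `cpg_only = TRUE`, only strings satisfying the CpG-context constraint
#' are returned: every M must be followed by a G whenever a successor position
#' exists (a terminal M is allowed, since its successor lies outside the
#' k-mer).  Note that unmodified strings (no M at all) satisfy the constraint
#' vacuously, so the CpG-valid set contains all 4^k unmodified k-mers plus
#' the modified ones; for k = 6 this gives 6765 strings, of which 2669
#' contain at least one M.
#'
#' @param alphabet A `mod_alphabet`, or a character vector of letters.
#' @param k Context length; defaults to the alphabet's `k`.
#' @param cpg_only If `TRUE`, keep only strings where every non-terminal M is
#'   followed by G.
#' @return Character vector of k-mers, lexicographically sorted in the
#'   alphabet's letter order.
#' @examples
#' length(enumerate_kmers(c("A", "C", "G", "T"), k = 6))        # 4096
#' length(enumerate_kmers(mod_alphabet(), k = 6))               # 15625
#' @export
enumerate_kmers <- function(alphabet = mod_alphabet(), k = NULL,
                            cpg_only = FALSE) {
  letters <- if (inherits(alphabet, "mod_alphabet")) alphabet$letters
             else as.character(alphabet)
  if (is.null(k))
    k <- if (inherits(alphabet, "mod_alphabet")) alphabet$k else 6L
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, letters, simplify = FALSE)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, rev(grid))
  if (cpg_only && "M" %in% letters) kmers <- kmers[is_cpg_context(kmers)]
  kmers
}

## TRUE iff every M is followed by G when a successor position exists.
is_cpg_context <- function(kmers) {
  !grepl("M(?!G)(?=.)", kmers, perl = TRUE)
}

#' Validate modified k-mers
#'
#' A valid modified k-mer is a string over \{A,C,G,T,M\} in which every M is
#' followed by G whenever a successor position exists (the CpG-context
#' constraint for 5mC).
#'
#' @param kmers Character vector.
#' @param k Required length, or `NULL` to accept any length.
#' @return Logical vector.
#' @export
is_valid_kmer <- function(kmers, k = 6L) {
  ok <- grepl("^[ACGTM]+$", kmers) & is_cpg_context(kmers)
  if (!is.null(k)) ok <- ok & nchar(kmers) == as.integer(k)
  ok
}

#' All modified CpG-context k-mers
#'
#' The universe of k-mers containing at least one M, under the CpG-context
#' constraint.  For k = 6 there are exactly 2669 of them.
#'
#' @param k Context length (default 6).
#' @return Character vector.
#' @export
all_modified_kmers <- function(k = 6L) {
  kmers <- enumerate_kmers(mod_alphabet(k = max(2L, k)), k = k,
                           cpg_only = TRUE)
  kmers[grepl("M", kmers, fixed = TRUE)]
}

#' Construct and validate a methylated window
#'
#' A methyl window is the (2k-1)-mer (11-mer for k = 6) centred on a single
#' methylated CpG: the centre position carries the M, the following position
#' a G, and no other M is permitted (windows overlapping a second methylated
#' site are outside the single-modification setting).  Pulling the window
#' through the pore yields its k overlapping constituent k-mers, each
#' containing the centre M.
#'
#' @param seq Character vector of window strings.
#' @param k Pore context length (default 6).
#' @return `seq`, invisibly classed as `methyl_window`, or an error.
#' @examples
#' methyl_window("GATTTMGCAAC")
#' @export
methyl_window <- function(seq, k = 6L) {
  bad <- !is_valid_window(seq, k = k)
  if (any(bad))
    stop("malformed methyl window(s): ", paste(seq[bad], collapse = ", "),
         " (need length ", 2L * k - 1L, ", centre M, centre+1 G, single M)")
  structure(seq, class = "methyl_window")
}

#' @rdname methyl_window
#' @export
is_valid_window <- function(seq, k = 6L) {
  k <- as.integer(k)
  w <- 2L * k - 1L
  nchar(seq) == w &
    grepl("^[ACGTM]+$", seq) &
    substr(seq, k, k) == "M" &
    substr(seq, k + 1L, k + 1L) == "G" &
    !grepl("M", paste0(substr(seq, 1L, k - 1L),
                       substr(seq, k + 1L, w)), fixed = TRUE)
}

#' Decompose a methyl window into its constituent k-mers
#'
#' The k overlapping k-mers, in pore order, that arise from pulling the
#' window through the pore; each contains the centre M.
#'
#' @param w A single window string (validated).
#' @param k Pore context length (default 6).
#' @return Character vector of k k-mers.
#' @examples
#' decompose_window("GATTTMGCAAC")
#' @export
decompose_window <- function(w, k = 6L) {
  if (length(w) != 1L) stop("decompose_window takes a single window")
  if (!is_valid_window(w, k = k))
    stop("malformed methyl window: ", w)
  k <- as.integer(k)
  substring(w, 1L:k, k:(2L * k - 1L))
}

#' Replace methylation marks with plain cytosine
#'
#' @param x Character vector of k-mers or windows.
#' @return `x` with every M replaced by C.
#' @export
unmethylate <- function(x) gsub("M", "C", x, fixed = TRUE)

## Dinucleotide vocabulary: ordered pairs over {A,C,G,T,M} that can occur in
## CpG-context sequence.  M can never be followed by A, C, T or M, leaving
## 25 - 4 = 21 symbols; 5 adjacent positions x 21 symbols = 105 features,
## consistent with the printed feature count.
DI_VOCAB <- local({
  pairs <- as.vector(outer(MOD_LETTERS, MOD_LETTERS,
                           function(a, b) paste0(a, b)))
  pairs <- pairs[order(match(substr(pairs, 1, 1), MOD_LETTERS),
                       match(substr(pairs, 2, 2), MOD_LETTERS))]
  setdiff(pairs, c("MA", "MC", "MT", "MM"))
})

#' Featurize modified 6-mers for the emission amortizer
#'
#' Binary featurization of length 141 = 30 + 105 + 6, laid out as:
#' \describe{
#'   \item{mononucleotide block (30)}{one-hot of each of the 6 positions over
#'     A<C<G<T<M;}
#'   \item{dinucleotide block (105)}{one-hot of each of the 5 adjacent
#'     ordered pairs over the 21-symbol CpG-context dinucleotide vocabulary
#'     (MA, MC, MT, MM cannot occur);}
#'   \item{C/M indicator block (6)}{bit i is 1 iff position i holds C or M,
#'     encoding that M is chemically a modified cytosine.}
#' }
#' Feature order is fixed (position-major, letters A<C<G<T<M within a
#' position) so that serialized predictors are stable.
#'
#' @param kmers Character vector of valid modified (or unmodified) CpG-context
#'   6-mers.
#' @return A binary integer matrix, one row per k-mer, 141 columns.
#' @examples
#' f <- featurize_kmer("CGAAMG")
#' sum(f[1:30]); sum(f[31:135]); f[136:141]
#' @export
featurize_kmers <- function(kmers) {
  k <- 6L
  if (any(nchar(kmers) != k))
    stop("featurization is defined for k = 6 only")
  if (!all(is_valid_kmer(kmers, k = k)))
    stop("invalid k-mer(s): ",
         paste(kmers[!is_valid_kmer(kmers, k = k)], collapse = ", "))
  n <- length(kmers)
  chars <- matrix(match(unlist(strsplit(kmers, "", fixed = TRUE)),
                        MOD_LETTERS), nrow = n, byrow = TRUE)
  mono <- matrix(0L, n, 5L * k)
  for (pos in 1:k)
    mono[cbind(seq_len(n), (pos - 1L) * 5L + chars[, pos])] <- 1L
  di <- matrix(0L, n, 21L * (k - 1L))
  for (pos in 1:(k - 1L)) {
    sym <- paste0(MOD_LETTERS[chars[, pos]], MOD_LETTERS[chars[, pos + 1L]])
    di[cbind(seq_len(n), (pos - 1L) * 21L + match(sym, DI_VOCAB))] <- 1L
  }
  cm <- matrix(as.integer(chars == 2L | chars == 5L), n, k)
  out <- cbind(mono, di, cm)
  rownames(out) <- kmers
  out
}

#' @rdname featurize_kmers
#' @param kmer A single k-mer.
#' @return `featurize_kmer` returns a length-141 integer vector.
#' @export
featurize_kmer <- function(kmer) {
  stopifnot(length(kmer) == 1L)
  drop(featurize_kmers(kmer))
}

#' One-hot Hamming distance between two windows
#'
#' Distance between the per-position five-symbol one-hot encodings of two
#' equal-length strings; a single substituted position flips two bits, so the
#' distance equals twice the number of mismatched positions.
#'
#' @param a,b Strings of equal length over \{A,C,G,T,M\}.
#' @return Non-negative even integer.
#' @examples
#' onehot_hamming("GATTTMGCAAC", "AATTTMGCAAC")  # 2
#' @export
onehot_hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch: ", a, " vs ", b)
  2L * sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
           strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Novelty of a window relative to a training set
#'
#' Mean one-hot Hamming distance from `w` to the unique windows of the
#' training set.  Duplicated training windows are deduplicated before
#' averaging, so the score depends only on the set of distinct windows.
#' High scores mark high-novelty test cases.
#'
#' @param w A window string.
#' @param training Character vector of training windows (non-empty).
#' @return Non-negative number.
#' @export
novelty_score <- function(w, training) {
  training <- unique(training)
  if (length(training) == 0L) stop("empty training set")
  wc <- strsplit(w, "", fixed = TRUE)[[1L]]
  tc <- strsplit(training, "", fixed = TRUE)
  if (any(lengths(tc) != length(wc))) stop("length mismatch")
  mean(vapply(tc, function(x) 2 * sum(x != wc), numeric(1)))
}
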