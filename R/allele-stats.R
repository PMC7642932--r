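# Alignment front end: derive the inputs of the statistic -- sample size n,
# number of distinct alleles m, and the average pairwise nucleotide
# difference theta_pi -- from an aligned set of equal-length sequences.

#' Read an aligned FASTA file into a tibble
#'
#' Thin wrapper over `Biostrings::readBStringSet()` (a byte-level set, so gap
#' and ambiguity characters pass through untouched). Sequences are not
#' validated here; see [summarize_alignment()].
#'
#' @param path Path to a FASTA file of aligned, equal-length sequences.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble::tibble(id = names(x), sequence = unname(as.character(x)))
}

# normalise a sequence for comparison: uppercase, RNA U -> T
normalize_seq <- function(s) {
  chartr("U", "T", toupper(s))
}

#' Number of differing positions between two aligned sequences
#'
#' Counts positions at which the two sequences differ. Under the default
#' `"pairwise-deletion"` policy, any column where either character is outside
#' `{A, C, G, T}` (after uppercasing and mapping U to T) is skipped; under
#' `"strict"`, such characters are an error. Comparison is case-insensitive.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @param policy `"pairwise-deletion"` (default) or `"strict"`.
#' @return A non-negative integer count.
#' @examples
#' pairwise_dist("ACGT", "ACGA")  # 1
#' pairwise_dist("AC-T", "ACGT")  # 0: the gap column is skipped
#' @export
pairwise_dist <- function(a, b, policy = c("pairwise-deletion", "strict")) {
  policy <- match.arg(policy)
  if (nchar(a) != nchar(b)) {
    stop("pairwise_dist(): sequences differ in length (", nchar(a), " vs ",
         nchar(b), "); input must be aligned", call. = FALSE)
  }
  ca <- strsplit(normalize_seq(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(normalize_seq(b), "", fixed = TRUE)[[1]]
  ok_a <- ca %in% c("A", "C", "G", "T")
  ok_b <- cb %in% c("A", "C", "G", "T")
  if (policy == "strict" && !all(ok_a & ok_b)) {
    stop("pairwise_dist(): non-ACGT character under strict policy", call. = FALSE)
  }
  keep <- ok_a & ok_b
  sum(ca[keep] != cb[keep])
}

#' Summarise an alignment into (n, L, m, theta_pi)
#'
#' Computes the sample size `n`, alignment length `L`, the number of distinct
#' alleles `m` (distinct full-length sequences after case/U normalisation;
#' gap characters participate in identity), and the average pairwise
#' difference `theta_pi = 2 / (n (n + 1)) * sum_{i < j} dist(D_i, D_j)`.
#'
#' The `n (n + 1)` denominator is this statistic's native convention
#' (`convention = "paper"`, the default). The conventional nucleotide
#' diversity estimator averages over the `n (n - 1) / 2` pairs and uses
#' `n (n - 1)`; select it with `convention = "tajima"`. The two differ by a
#' factor `(n - 1)/(n + 1)`; neither is silently corrected to the other.
#'
#' @param x A tibble with columns `id` and `sequence` (as from
#'   [read_alignment()]), or a named character vector of sequences.
#' @param convention `"paper"` (denominator `n (n + 1)`) or `"tajima"`
#'   (denominator `n (n - 1)`).
#' @param policy Site-comparison policy, see [pairwise_dist()].
#' @return A one-row tibble with columns `n`, `L`, `m`, `theta_pi`,
#'   `convention`, `policy`.
#' @examples
#' aln <- c(s1 = "ACGTACGT", s2 = "ACGTACGA", s3 = "ACGTACGT")
#' summarize_alignment(aln)
#' @export
summarize_alignment <- function(x, convention = c("paper", "tajima"),
                                policy = c("pairwise-deletion", "strict")) {
  convention <- match.arg(convention)
  policy <- match.arg(policy)
  if (is.data.frame(x)) {
    seqs <- x$sequence
    ids <- x$id
  } else {
    seqs <- unname(as.character(x))
    ids <- names(x)
  }
  seqs <- unname(seqs)
  n <- length(seqs)
  if (n < 2L) stop("summarize_alignment(): need at least 2 sequences", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("summarize_alignment(): sequences are not equal length; ",
         "input must be an alignment", call. = FALSE)
  }
  if (!is.null(ids) && anyDuplicated(ids)) {
    warning("summarize_alignment(): duplicate sequence IDs")
  }
  norm <- vapply(seqs, normalize_seq, character(1), USE.NAMES = FALSE)
  m <- length(unique(norm))
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      total <- total + pairwise_dist(norm[i], norm[j], policy = policy)
    }
  }
  denom <- if (convention == "paper") n * (n + 1) else n * (n - 1)
  tibble::tibble(n = n, L = lens[1], m = m, theta_pi = 2 * total / denom,
                 convention = convention, policy = policy)
}

#' Fu's Fs straight from an alignment
#'
#' Convenience chain: [summarize_alignment()] then [fu_fs()] with
#' `theta = theta_pi`.
#'
#' @inheritParams summarize_alignment
#' @inheritParams fu_fs
#' @return A one-row tibble: the alignment summary joined with the tidied
#'   `fs_result`.
#' @export
alignment_fs <- function(x, convention = c("paper", "tajima"),
                         policy = c("pairwise-deletion", "strict"),
                         method = c("auto", "exact", "asymptotic")) {
  summ <- summarize_alignment(x, convention = convention, policy = policy)
  if (summ$theta_pi <= 0) {
    stop("alignment_fs(): theta_pi is zero (all sequences identical); ",
         "Fs is undefined", call. = FALSE)
  }
  res <- fu_fs(summ$n, summ$m, summ$theta_pi, method = method)
  dplyr::bind_cols(summ, tidy(res)[, c("s_prime", "t_prime", "fs", "branch", "method")])
}
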