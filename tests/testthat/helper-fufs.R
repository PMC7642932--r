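# Shared fixtures and independent oracles used across the suite.

# Exact rational evaluation of the Ewens log partial sums for theta = p/q,
# through the package's big-integer layer (an arithmetic path fully disjoint
# from the floating log-sum-exp engine it checks).
rational_log_partials <- function(n, m, p_num, q_den) {
  fufs:::fs_partials_rational(n, m, p_num, q_den)
}

rational_fs <- function(n, m, p_num, q_den) {
  parts <- rational_log_partials(n, m, p_num, q_den)
  parts$log_upper - parts$log_lower
}

# a small aligned fixture: 5 sequences, 8 columns, 3 distinct alleles
example_alignment <- function() {
  c(a1 = "ACGTACGT",
    a2 = "ACGTACGT",
    a3 = "ACCTACGT",   # 1 diff vs a1
    a4 = "ACCTACGA",   # 2 diffs vs a1
    a5 = "ACGTACGT")
}

write_fasta <- function(seqs, path) {
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  path
}
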