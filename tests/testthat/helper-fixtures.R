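# shared fixtures built in code

standin_fasta <- function() {
  system.file("extdata", "prrc2b_long_synthetic.fasta",
              package = "toppreserve")
}

standin_seq <- function() {
  read_protein_fasta(standin_fasta())$seq[1]
}

# brute-force hypergeometric right tail by enumerating all draws of size n
# from a universe of N with m annotated items
enum_overlap_p <- function(x, n, m, N) {
  universe <- seq_len(N)
  annotated <- seq_len(m)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2L, function(d) length(intersect(d, annotated))) >= x)
}

# hand step-up BH: q_i = min over j >= i of p_(j) * m / j
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q)[order(o)]
}

# all permutations of a small vector (rows of the returned matrix)
gtools_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], gtools_perms(v[-i]))
  }))
}

# a tiny deterministic IP-MS experiment for rule-level tests
toy_ipms <- function() {
  intensities <- tibble::tibble(
    protein = c("kept2of3", "one_per_group", "decoy", "contam", "full"),
    bait_1 = c(10, 10, 10, 10, 10),
    bait_2 = c(12, NA, 12, 12, 12),
    bait_3 = c(NA, NA, 14, 14, 14),
    ctrl_1 = c(NA, 8, 8, 8, 8),
    ctrl_2 = c(NA, NA, 9, 9, 9),
    ctrl_3 = c(NA, NA, 10, 10, 10)
  )
  samples <- tibble::tibble(
    sample = c("bait_1", "bait_2", "bait_3", "ctrl_1", "ctrl_2", "ctrl_3"),
    group = rep(c("bait", "ctrl"), each = 3),
    replicate = rep(1:3, 2)
  )
  proteins <- tibble::tibble(
    protein = intensities$protein,
    n_peptides = c(3L, 3L, 5L, 5L, 4L),
    is_decoy = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    is_contaminant = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  ipms_experiment(intensities, samples, proteins)
}
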