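# Shared builders for small deterministic fixtures.

# tiny residue-matched complex: square-ish chain, 2-atom ligand
tiny_complex <- function(n_res = 6, t = 0, lig_offset = c(0, 0, 4)) {
  ca <- cbind(3.8 * seq_len(n_res), 0, 0)
  heavy <- matrix(0, 2 * n_res, 3)
  heavy[2 * seq_len(n_res) - 1, ] <- ca
  heavy[2 * seq_len(n_res), ] <- ca + matrix(c(0, 1.5, 0), n_res, 3,
                                             byrow = TRUE)
  prot <- protein_structure(paste(rep("A", n_res), collapse = ""), ca,
                            heavy, rep(seq_len(n_res), each = 2))
  lg <- ligand_graph(c("C", "O"), rbind(c(1, 2)))
  lig <- rbind(ca[n_res %/% 2, ] + lig_offset,
               ca[n_res %/% 2, ] + lig_offset + c(1.5, 0, 0))
  complex_structure(prot, lig, lg, t = t)
}

# endpoint oracle corrupted by per-call Gaussian noise; calls are
# deterministic in (seed, call index) so two solvers consuming the same
# number of calls see identical noise (common random numbers)
noisy_oracle <- function(x1, sigma, seed) {
  count <- new.env()
  count$n <- 0L
  function(x, t) {
    count$n <- count$n + 1L
    set.seed(seed + count$n)
    x1 + matrix(rnorm(length(x1), sd = sigma), nrow(x1), 3)
  }
}

# total variance of final states over a list of runs
final_state_variance <- function(finals) {
  m <- Reduce(`+`, finals) / length(finals)
  mean(vapply(finals, function(f) mean((f - m)^2), numeric(1)))
}

# textbook regression metrics written out longhand (independent of
# regression_metrics internals)
longhand_metrics <- function(p, o) {
  n <- length(p)
  pm <- sum(p) / n; om <- sum(o) / n
  pearson <- sum((p - pm) * (o - om)) /
    sqrt(sum((p - pm)^2) * sum((o - om)^2))
  rp <- rank(p); ro <- rank(o)
  rpm <- sum(rp) / n; rom <- sum(ro) / n
  spearman <- sum((rp - rpm) * (ro - rom)) /
    sqrt(sum((rp - rpm)^2) * sum((ro - rom)^2))
  list(pearson = pearson, spearman = spearman,
       rmse = sqrt(sum((p - o)^2) / n), mae = sum(abs(p - o)) / n)
}
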