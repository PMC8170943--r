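#' Generate a planted-block synthetic benchmark dataset
#'
#' Emulates the benchmark triple (drug similarity, disease similarity,
#' interaction matrix) with planted block structure instantiating the
#' working hypothesis of similarity-based repositioning: similar drugs share
#' indications. Drugs and diseases are assigned near-uniformly to
#' `k_blocks` matched blocks; an interaction occurs with probability `p_in`
#' when the drug's and disease's blocks match and `p_out` otherwise.
#' Similarities are `sim_in` within blocks and `sim_out` between, plus
#' symmetric Gaussian noise (sd `sim_noise`), clipped to \[0, 1\] with unit
#' diagonal. Entity IDs are synthesized as `DRUG####` / `DIS####`.
#'
#' @param m,n number of drugs and diseases (each >= `k_blocks`).
#' @param k_blocks number of matched blocks.
#' @param p_in,p_out interaction probabilities inside / outside matched
#'   blocks (`0 <= p_out < p_in <= 1`).
#' @param sim_in,sim_out mean within- and between-block similarity.
#' @param sim_noise standard deviation of the similarity noise.
#' @param seed integer seed; the generator is fully reproducible.
#' @return A list with `dataset` (a [benchmark_dataset()]) and `truth`
#'   (list of `drug_blocks`, `disease_blocks`, and the generating `config`).
#' @examples
#' sim <- synthetic_benchmark(m = 30, n = 20, k_blocks = 3, seed = 1)
#' summary(sim$dataset)
#' @export
synthetic_benchmark <- function(m = 200, n = 150, k_blocks = 5,
                                p_in = 0.3, p_out = 0.02,
                                sim_in = 0.8, sim_out = 0.1,
                                sim_noise = 0.05, seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    fail("need 0 <= p_out < p_in <= 1")
  if (any(c(sim_in, sim_out) < 0) || any(c(sim_in, sim_out) > 1))
    fail("sim_in and sim_out must be in [0, 1]")
  if (sim_noise < 0) fail("sim_noise must be non-negative")
  if (m < k_blocks || n < k_blocks) fail("m and n must be >= k_blocks")

  with_seed(seed, {
    drug_blocks <- sample(rep(seq_len(k_blocks), length.out = m))
    disease_blocks <- sample(rep(seq_len(k_blocks), length.out = n))
    match_ <- outer(drug_blocks, disease_blocks, "==")
    I <- matrix(stats::rbinom(m * n, 1, ifelse(match_, p_in, p_out)), m, n)
    drug_sim <- block_similarity(drug_blocks, sim_in, sim_out, sim_noise)
    disease_sim <- block_similarity(disease_blocks, sim_in, sim_out, sim_noise)
    ds <- benchmark_dataset(
      drug_sim, disease_sim, I,
      drugs = sprintf("DRUG%04d", seq_len(m)),
      diseases = sprintf("DIS%04d", seq_len(n))
    )
    list(dataset = ds,
         truth = list(drug_blocks = drug_blocks,
                      disease_blocks = disease_blocks,
                      config = list(m = m, n = n, k_blocks = k_blocks,
                                    p_in = p_in, p_out = p_out,
                                    sim_in = sim_in, sim_out = sim_out,
                                    sim_noise = sim_noise, seed = seed)))
  })
}

block_similarity <- function(blocks, sim_in, sim_out, sim_noise) {
  k <- length(blocks)
  S <- ifelse(outer(blocks, blocks, "=="), sim_in, sim_out)
  if (sim_noise > 0) {
    E <- matrix(stats::rnorm(k * k, 0, sim_noise), k, k)
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    S <- S + E
  }
  S[S < 0] <- 0; S[S > 1] <- 1
  diag(S) <- 1
  S
}

#' Permute the interaction matrix (null-model control)
#'
#' Shuffles the 1-entries of the interaction matrix uniformly over all
#' cells, preserving the total interaction count and leaving both similarity
#' matrices untouched. Running the pipeline on the permuted dataset breaks
#' the link between similarity structure and interactions, so prediction
#' performance should fall to chance.
#'
#' @param ds a [benchmark_dataset()].
#' @param seed integer seed.
#' @return A new [benchmark_dataset()] with permuted interactions.
#' @export
permute_interactions <- function(ds, seed = 1) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  I <- ds$interactions
  npos <- sum(I == 1)
  I_new <- matrix(0, nrow(I), ncol(I))
  ones <- with_seed(seed, sample(length(I), npos))
  I_new[ones] <- 1
  benchmark_dataset(ds$drug_sim, ds$disease_sim, I_new, ds$drugs, ds$diseases)
}

#' Save ground-truth block labels alongside a dataset directory
#'
#' @param truth the `truth` element from [synthetic_benchmark()].
#' @param directory dataset directory.
#' @return Invisibly, the file path written.
#' @export
save_ground_truth <- function(truth, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(directory, "ground_truth.tsv")
  df <- rbind(
    data.frame(entity = sprintf("DRUG%04d", seq_along(truth$drug_blocks)),
               block = truth$drug_blocks),
    data.frame(entity = sprintf("DIS%04d", seq_along(truth$disease_blocks)),
               block = truth$disease_blocks)
  )
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}
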