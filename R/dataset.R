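#' Assemble and validate a drug-disease benchmark dataset
#'
#' Bundles the three matrices a drug-repositioning benchmark consists of: a
#' drug-drug similarity matrix `S_D` (m x m), a disease-disease similarity
#' matrix `S_d` (n x n) and a binary drug-disease interaction matrix `I`
#' (m x n), together with the ordered drug and disease identifier lists that
#' define row/column order everywhere.
#'
#' Validation enforces: unique IDs matching matrix dimensions; interaction
#' entries in \{0, 1\}; similarity matrices symmetric to `tol` with unit
#' diagonal. Similarity entries slightly outside \[0, 1\] (rounding artifacts
#' in public deposits) are clipped with a warning; asymmetry or a wrong
#' diagonal beyond `tol` is an error.
#'
#' @param drug_sim numeric m x m drug similarity matrix.
#' @param disease_sim numeric n x n disease similarity matrix.
#' @param interactions numeric/integer m x n binary interaction matrix.
#' @param drugs character vector of m unique drug IDs (e.g. DrugBank
#'   accessions such as `"DB00399"`).
#' @param diseases character vector of n unique disease IDs (e.g. OMIM-style
#'   IDs such as `"D254500"`).
#' @param tol absolute tolerance for symmetry and unit-diagonal checks.
#' @return An object of class `benchmark_dataset`: a list with elements
#'   `drug_sim`, `disease_sim`, `interactions`, `drugs`, `diseases`.
#' @examples
#' ds <- benchmark_dataset(
#'   drug_sim = diag(2), disease_sim = diag(3),
#'   interactions = matrix(c(1, 0, 0, 1, 0, 0), 2, 3),
#'   drugs = c("DRUG0001", "DRUG0002"),
#'   diseases = c("DIS0001", "DIS0002", "DIS0003")
#' )
#' summary(ds)
#' @export
benchmark_dataset <- function(drug_sim, disease_sim, interactions,
                              drugs, diseases, tol = 1e-10) {
  drug_sim <- as.matrix(drug_sim)
  disease_sim <- as.matrix(disease_sim)
  interactions <- as.matrix(interactions)
  drugs <- as.character(drugs)
  diseases <- as.character(diseases)

  m <- length(drugs); n <- length(diseases)
  if (m == 0L || n == 0L) fail("dataset must have at least one drug and one disease")
  if (anyDuplicated(drugs)) fail("duplicate drug IDs")
  if (anyDuplicated(diseases)) fail("duplicate disease IDs")
  if (!all(dim(interactions) == c(m, n)))
    fail("interaction matrix is %dx%d but there are %d drugs and %d diseases",
         nrow(interactions), ncol(interactions), m, n)
  if (!all(interactions %in% c(0, 1)))
    fail("interaction matrix has non-binary entries")
  storage.mode(interactions) <- "double"

  drug_sim <- validate_similarity(drug_sim, m, "drug", tol)
  disease_sim <- validate_similarity(disease_sim, n, "disease", tol)

  dimnames(drug_sim) <- list(drugs, drugs)
  dimnames(disease_sim) <- list(diseases, diseases)
  dimnames(interactions) <- list(drugs, diseases)

  structure(
    list(drug_sim = drug_sim, disease_sim = disease_sim,
         interactions = interactions, drugs = drugs, diseases = diseases),
    class = "benchmark_dataset"
  )
}

validate_similarity <- function(S, k, what, tol) {
  if (!all(dim(S) == c(k, k)))
    fail("%s similarity matrix must be %dx%d, got %dx%d", what, k, k, nrow(S), ncol(S))
  if (any(!is.finite(S))) fail("%s similarity matrix has non-finite entries", what)
  if (max(abs(S - t(S))) > tol)
    fail("%s similarity matrix is asymmetric beyond tolerance %g", what, tol)
  if (max(abs(diag(S) - 1)) > tol)
    fail("%s similarity matrix diagonal differs from 1 beyond tolerance %g", what, tol)
  if (any(S < 0) || any(S > 1)) {
    warning(sprintf("%s similarity entries outside [0,1] clipped", what), call. = FALSE)
    S[S < 0] <- 0; S[S > 1] <- 1
  }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Load a benchmark dataset from a directory
#'
#' Reads the three matrices and two ID lists making up a benchmark dataset.
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`fdataset_layout`}{headerless tab-delimited numeric matrices
#'     (`drug_sim.txt`, `disease_sim.txt`, `interactions.txt`) with IDs in
#'     sidecar one-per-line files (`drugs.txt`, `diseases.txt`).}
#'   \item{`generic_tsv`}{the same three matrix files carrying a header row
#'     and a first column of IDs; no sidecar files needed.}
#' }
#'
#' @param directory path to the dataset directory.
#' @param dialect `"fdataset_layout"` (default) or `"generic_tsv"`.
#' @return A validated [benchmark_dataset()].
#' @seealso [save_benchmark()]
#' @export
load_benchmark <- function(directory, dialect = c("fdataset_layout", "generic_tsv")) {
  dialect <- match.arg(dialect)
  need <- function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) fail("missing dataset file: %s", p)
    p
  }
  if (dialect == "fdataset_layout") {
    drugs <- readLines(need("drugs.txt"))
    diseases <- readLines(need("diseases.txt"))
    rd <- function(f) as.matrix(utils::read.table(need(f), sep = "\t", header = FALSE))
    ds <- rd("drug_sim.txt"); dd <- rd("disease_sim.txt"); ii <- rd("interactions.txt")
  } else {
    rd <- function(f) {
      x <- utils::read.table(need(f), sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE)
      as.matrix(x)
    }
    ds <- rd("drug_sim.tsv"); dd <- rd("disease_sim.tsv"); ii <- rd("interactions.tsv")
    drugs <- rownames(ii); diseases <- colnames(ii)
  }
  benchmark_dataset(ds, dd, ii, drugs, diseases)
}

#' Save a benchmark dataset to a directory
#'
#' Writes the dataset in the requested dialect so that [load_benchmark()]
#' round-trips it: bit-identically for the binary interaction matrix and to
#' better than 1e-12 for the similarity matrices.
#'
#' @param ds a [benchmark_dataset()].
#' @param directory output directory (created if absent).
#' @param dialect on-disk layout, see [load_benchmark()].
#' @return Invisibly, the directory path.
#' @export
save_benchmark <- function(ds, directory,
                           dialect = c("fdataset_layout", "generic_tsv")) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  dialect <- match.arg(dialect)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) fail("cannot create directory: %s", directory)
  fmt <- function(M) apply(M, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                           scientific = FALSE),
                                                    collapse = "\t"))
  if (dialect == "fdataset_layout") {
    writeLines(ds$drugs, file.path(directory, "drugs.txt"))
    writeLines(ds$diseases, file.path(directory, "diseases.txt"))
    writeLines(fmt(ds$drug_sim), file.path(directory, "drug_sim.txt"))
    writeLines(fmt(ds$disease_sim), file.path(directory, "disease_sim.txt"))
    writeLines(fmt(ds$interactions), file.path(directory, "interactions.txt"))
  } else {
    wr <- function(M, f) {
      df <- data.frame(id = rownames(M), M, check.names = FALSE)
      utils::write.table(df, file.path(directory, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wr(ds$drug_sim, "drug_sim.tsv")
    wr(ds$disease_sim, "disease_sim.tsv")
    wr(ds$interactions, "interactions.tsv")
  }
  invisible(directory)
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("Drug-disease benchmark dataset: %d drugs x %d diseases, %d known interactions (density %.4f)\n",
              length(x$drugs), length(x$diseases), sum(x$interactions),
              mean(x$interactions)))
  invisible(x)
}

#' Summarize a benchmark dataset
#'
#' @param object a [benchmark_dataset()].
#' @param ... unused.
#' @return A list with `n_drugs`, `n_diseases`, `n_interactions`, `density`.
#' @export
summary.benchmark_dataset <- function(object, ...) {
  out <- list(
    n_drugs = length(object$drugs),
    n_diseases = length(object$diseases),
    n_interactions = as.integer(sum(object$interactions)),
    density = mean(object$interactions)
  )
  class(out) <- "summary.benchmark_dataset"
  out
}

#' @export
print.summary.benchmark_dataset <- function(x, ...) {
  cat(sprintf("drugs: %d\ndiseases: %d\nknown interactions: %d\ndensity: %.4f\n",
              x$n_drugs, x$n_diseases, x$n_interactions, x$density))
  invisible(x)
}
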