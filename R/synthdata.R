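# Planted-signal synthetic data.
#
# Molecules are composed from curated ring-core fragments plus small
# substituent decorations, so every emitted SMILES is chemically valid
# without a rejection loop. Cores are grouped into structural classes that
# differ in heteroatom content (pure carbocycles / oxygen heterocycles /
# nitrogen heterocycles), and the DDI network links each drug pair with a
# probability that depends only on the two classes. Structure therefore
# genuinely predicts interaction — the property the multi-view model is
# meant to exploit — while scaffold splitting still holds out whole ring
# frameworks, because each class contains several distinct cores.

.FRAGMENT_CLASSES <- list(
  carbocycle = c(
    "c1ccccc1",              # benzene
    "c1ccc2ccccc2c1",        # naphthalene
    "C1CCCCC1",              # cyclohexane
    "C1CCCC1",               # cyclopentane
    "C1Cc2ccccc2C1",         # indane
    "C1CCc2ccccc2C1",        # tetralin
    "c1ccc(-c2ccccc2)cc1"    # biphenyl
  ),
  oxygen_heterocycle = c(
    "c1ccoc1",               # furan
    "C1CCOC1",               # tetrahydrofuran
    "C1CCOCC1",              # tetrahydropyran
    "C1COCCO1",              # 1,4-dioxane
    "c1ccc2occc2c1",         # benzofuran
    "C1Cc2ccccc2OC1",        # chromane
    "C1CCOCCC1"              # oxepane
  ),
  nitrogen_heterocycle = c(
    "c1ccncc1",              # pyridine
    "C1CCNC1",               # pyrrolidine
    "C1CCNCC1",              # piperidine
    "C1CNCCN1",              # piperazine
    "c1cncnc1",              # pyrimidine
    "c1ccc2ncccc2c1",        # quinoline
    "c1ccc2[nH]ccc2c1"       # indole
  )
)

# carbon/halogen substituents only, so decorations never blur the
# heteroatom signal that separates the classes
.DECORATIONS <- c("C", "CC", "CCC", "CCCC", "CC(C)C", "F", "Cl", "Br")

#' Specification of a synthetic DDI study
#'
#' @param n_drugs Number of drugs (default 200).
#' @param fragment_classes Named list of core-fragment SMILES per structural
#'   class (defaults to three classes distinguished by heteroatom content).
#' @param class_interaction_matrix Symmetric matrix of link probabilities
#'   per class pair. The default plants a well-separated signal: 0.9 within
#'   a class, 0.05 across classes.
#' @param decoration_rate Probability that a generated molecule carries a
#'   substituent at either attachment point (default 0.8).
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 200L,
                           fragment_classes = .FRAGMENT_CLASSES,
                           class_interaction_matrix = NULL,
                           decoration_rate = 0.8,
                           seed = 1L) {
  n_classes <- length(fragment_classes)
  if (is.null(class_interaction_matrix)) {
    class_interaction_matrix <- matrix(0.05, n_classes, n_classes)
    diag(class_interaction_matrix) <- 0.9
  }
  stopifnot(
    n_drugs >= 4L,
    n_classes >= 1L,
    nrow(class_interaction_matrix) == n_classes,
    isSymmetric(unname(class_interaction_matrix)),
    all(class_interaction_matrix >= 0 & class_interaction_matrix <= 1),
    decoration_rate >= 0, decoration_rate <= 1
  )
  if (is.null(names(fragment_classes))) {
    names(fragment_classes) <- paste0("class", seq_len(n_classes))
  }
  dimnames(class_interaction_matrix) <-
    list(names(fragment_classes), names(fragment_classes))
  structure(
    list(n_drugs = as.integer(n_drugs),
         fragment_classes = fragment_classes,
         class_interaction_matrix = class_interaction_matrix,
         decoration_rate = decoration_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# compose one decorated molecule: optional substituent prefix on the first
# core atom and/or suffix on the last; both attachments are valid SMILES for
# every core in the library
.compose_molecule <- function(core, prefix, suffix) {
  paste0(prefix, core, suffix)
}

#' Generate synthetic drug molecules
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `drug_id`, `smiles`, `class_label`; every
#'   SMILES parses, classes are assigned round-robin so sizes are balanced,
#'   and the draw is deterministic per seed.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- names(spec$fragment_classes)
  withr::with_seed(spec$seed, {
    class_label <- rep_len(classes, spec$n_drugs)
    smiles <- character(spec$n_drugs)
    for (d in seq_len(spec$n_drugs)) {
      cores <- spec$fragment_classes[[class_label[d]]]
      core <- cores[sample.int(length(cores), 1L)]
      prefix <- if (stats::runif(1) < spec$decoration_rate) {
        .DECORATIONS[sample.int(length(.DECORATIONS), 1L)]
      } else ""
      suffix <- if (stats::runif(1) < spec$decoration_rate) {
        .DECORATIONS[sample.int(length(.DECORATIONS), 1L)]
      } else ""
      smiles[d] <- .compose_molecule(core, prefix, suffix)
    }
    data.frame(
      drug_id = sprintf("D%04d", seq_len(spec$n_drugs)),
      smiles = smiles,
      class_label = class_label
    )
  })
}

#' Generate a planted-signal DDI network
#'
#' Each unordered drug pair is linked independently with the probability
#' given by the class-interaction matrix entry for the two drugs' classes.
#'
#' @param drugs Data frame from [generate_molecules()] (columns `drug_id`,
#'   `class_label`).
#' @param spec The same [synthetic_spec()].
#' @return A [ddi_network()] containing the positive links.
#' @export
generate_ddi <- function(drugs, spec) {
  stopifnot(inherits(spec, "synthetic_spec"),
            all(drugs$class_label %in% rownames(spec$class_interaction_matrix)))
  n <- nrow(drugs)
  pairs <- utils::combn(n, 2L)
  p <- spec$class_interaction_matrix[
    cbind(drugs$class_label[pairs[1L, ]], drugs$class_label[pairs[2L, ]])]
  linked <- withr::with_seed(spec$seed + 7L,
                             stats::runif(ncol(pairs)) < p)
  edges <- data.frame(
    drug_id_1 = drugs$drug_id[pairs[1L, linked]],
    drug_id_2 = drugs$drug_id[pairs[2L, linked]]
  )
  ddi_network(drugs$drug_id, edges)
}

#' Generate an unlabeled SMILES corpus for pretraining
#'
#' Enumerates core-fragment / decoration combinations (plus short acyclic
#' molecules), de-duplicates, and draws `n` of them — giving a varied,
#' fully parseable desk-scale stand-in for a large public molecule corpus.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @return Character vector of `n` unique SMILES strings.
#' @export
generate_pretrain_corpus <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  cores <- unlist(.FRAGMENT_CLASSES, use.names = FALSE)
  acyclic <- c("CCO", "CCCO", "CCN", "CCCN", "CCCC", "CCCCC", "CC(C)CC",
               "CCOCC", "CC(C)O", "CCCl", "CC(C)CO", "CCCBr", "CC(N)C",
               "CCOC(C)C", "CCCCCC", "CC(C)(C)C")
  pool <- unique(c(
    cores,
    acyclic,
    as.vector(outer(.DECORATIONS, cores, function(d, c) paste0(d, c))),
    as.vector(outer(cores, .DECORATIONS, paste0)),
    as.vector(outer(
      paste0(rep(.DECORATIONS, each = length(cores)), rep(cores,
                                                          length(.DECORATIONS))),
      .DECORATIONS, paste0))
  ))
  if (n > length(pool)) {
    stop("corpus pool exhausted: at most ", length(pool),
         " unique molecules available")
  }
  withr::with_seed(seed, sample(pool, n))
}
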