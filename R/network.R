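# The DDI network: drugs as nodes, known interactions as undirected links,
# plus the scaffold-based data splitting and negative sampling used for
# out-of-distribution link-prediction evaluation.

#' Construct a DDI network
#'
#' @param drug_ids Character vector of drug identifiers (defines node order).
#' @param edges Data frame of interacting pairs with columns `drug_id_1`,
#'   `drug_id_2` and optionally `label` (0/1; missing means 1). Self pairs
#'   are rejected; duplicate unordered pairs are collapsed.
#' @return An object of class `ddi_network` with `drug_ids`, `n` and
#'   `labeled_pairs` (data frame `i`, `j`, `y` with `i < j`, indices into
#'   `drug_ids`).
#' @export
ddi_network <- function(drug_ids, edges) {
  drug_ids <- as.character(drug_ids)
  stopifnot(!anyDuplicated(drug_ids))
  i <- match(as.character(edges$drug_id_1), drug_ids)
  j <- match(as.character(edges$drug_id_2), drug_ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(edges$drug_id_1[is.na(i)], edges$drug_id_2[is.na(j)]))
    stop("edge endpoints not in drug table: ", paste(bad, collapse = ", "))
  }
  if (any(i == j)) stop("self-interactions are not allowed")
  y <- if ("label" %in% names(edges)) as.integer(edges$label) else
    rep.int(1L, length(i))
  stopifnot(all(y %in% c(0L, 1L)))
  pairs <- data.frame(i = pmin(i, j), j = pmax(i, j), y = y)
  pairs <- pairs[!duplicated(pairs[c("i", "j")]), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(drug_ids = drug_ids, n = length(drug_ids),
                 labeled_pairs = pairs),
            class = "ddi_network")
}

#' @export
print.ddi_network <- function(x, ...) {
  cat(sprintf("<ddi_network> %d drugs, %d positive links, %d labeled pairs\n",
              x$n, sum(x$labeled_pairs$y == 1L), nrow(x$labeled_pairs)))
  invisible(x)
}

#' Dense adjacency matrix of a DDI network
#'
#' @param network A [ddi_network()].
#' @param links Optional data frame of pairs (`i`, `j`) to restrict the
#'   adjacency to (e.g. only train-split links); default: all positive links.
#' @return Symmetric 0/1 matrix with zero diagonal, `n x n`.
#' @export
adjacency_matrix <- function(network, links = NULL) {
  if (is.null(links)) {
    lp <- network$labeled_pairs
    links <- lp[lp$y == 1L, , drop = FALSE]
  }
  A <- matrix(0, network$n, network$n)
  if (nrow(links)) {
    A[cbind(links$i, links$j)] <- 1
    A[cbind(links$j, links$i)] <- 1
  }
  A
}

#' Scaffold-based train/validation/test split of drugs
#'
#' Drugs are grouped by their canonical Bemis-Murcko scaffold (acyclic
#' molecules form a single empty-scaffold group), the groups are shuffled
#' under the given seed, and whole groups are assigned greedily: to train
#' until at least `ratios[1]` of the drugs are covered, then to validation
#' until `ratios[1] + ratios[2]`, with the remainder becoming the test set.
#' No scaffold ever straddles two splits, which is the point: test molecules
#' present ring frameworks never seen in training.
#'
#' @param drugs Data frame with columns `drug_id` and `smiles` (optionally a
#'   precomputed `scaffold` column to skip recomputation).
#' @param ratios Numeric length-3 target fractions summing to 1.
#' @param seed Integer seed controlling the group shuffle.
#' @return An object of class `split_assignment`: list with `drug_split`
#'   (named character vector, values in train/valid/test), `scaffold` (named
#'   vector of scaffold keys), `seed`, and `flags` noting empty splits.
#' @export
scaffold_split <- function(drugs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8,
            all(ratios >= 0))
  ids <- as.character(drugs$drug_id)
  scaf <- if ("scaffold" %in% names(drugs)) {
    as.character(drugs$scaffold)
  } else {
    vapply(drugs$smiles, function(s) {
      sc <- bemis_murcko_scaffold(s)
      if (!is.character(sc)) stop("unparseable SMILES in scaffold_split: ", s)
      sc
    }, character(1), USE.NAMES = FALSE)
  }
  groups <- split(seq_along(ids), scaf)
  ord <- withr::with_seed(seed, sample.int(length(groups)))
  groups <- groups[ord]
  n <- length(ids)
  assign <- character(n)
  cum <- 0L
  for (grp in groups) {
    lab <- if (cum < ratios[1] * n) "train"
    else if (cum < (ratios[1] + ratios[2]) * n) "valid"
    else "test"
    assign[grp] <- lab
    cum <- cum + length(grp)
  }
  drug_split <- stats::setNames(assign, ids)
  structure(
    list(
      drug_split = drug_split,
      scaffold = stats::setNames(scaf, ids),
      seed = as.integer(seed),
      flags = list(empty_valid = !any(assign == "valid"),
                   empty_test = !any(assign == "test"))
    ),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  tab <- table(factor(x$drug_split, levels = c("train", "valid", "test")))
  cat(sprintf("<split_assignment> seed %d: train %d / valid %d / test %d\n",
              x$seed, tab[["train"]], tab[["valid"]], tab[["test"]]))
  invisible(x)
}

#' Assign DDI links to splits from their endpoint drugs
#'
#' A link inherits the most-held-out of its two endpoints (test > valid >
#' train), so every test link involves at least one drug whose scaffold was
#' never seen during training.
#'
#' @param network A [ddi_network()].
#' @param drug_split Named character vector (drug id -> train/valid/test),
#'   e.g. the `drug_split` element of [scaffold_split()].
#' @return Character vector, one of train/valid/test per row of
#'   `network$labeled_pairs`.
#' @export
split_links <- function(network, drug_split) {
  ids <- network$drug_ids
  missing <- setdiff(ids[unique(c(network$labeled_pairs$i,
                                  network$labeled_pairs$j))],
                     names(drug_split))
  if (length(missing)) {
    stop("drugs missing from drug_split: ", paste(missing, collapse = ", "))
  }
  si <- drug_split[ids[network$labeled_pairs$i]]
  sj <- drug_split[ids[network$labeled_pairs$j]]
  out <- ifelse(si == "test" | sj == "test", "test",
                ifelse(si == "valid" | sj == "valid", "valid", "train"))
  unname(out)
}

# unordered candidate pairs (i < j) eligible for a given split under the
# endpoint-inheritance rule, excluding known positive links
.negative_candidates <- function(network, drug_split, split) {
  lev <- drug_split[network$drug_ids]
  idx <- seq_len(network$n)
  cand <- utils::combn(idx, 2L)
  ci <- cand[1L, ]; cj <- cand[2L, ]
  li <- lev[ci]; lj <- lev[cj]
  keep <- switch(
    split,
    train = li == "train" & lj == "train",
    valid = (li == "valid" | lj == "valid") & li != "test" & lj != "test",
    test = li == "test" | lj == "test",
    stop("unknown split: ", split)
  )
  ci <- ci[keep]; cj <- cj[keep]
  lp <- network$labeled_pairs
  pos <- lp[lp$y == 1L, , drop = FALSE]
  pos_key <- pos$i * (network$n + 1L) + pos$j
  cand_key <- ci * (network$n + 1L) + cj
  free <- !(cand_key %in% pos_key)
  data.frame(i = ci[free], j = cj[free])
}

#' Sample negative (non-interacting) drug pairs per split
#'
#' Uniformly samples unordered non-adjacent drug pairs to serve as negative
#' examples for binary link prediction, split by split: train negatives use
#' only train drugs, validation negatives involve a validation drug and no
#' test drug, test negatives involve at least one test drug — mirroring how
#' positive links inherit splits in [split_links()]. Sampling is seeded per
#' split, so the train/validation draws are unaffected by the content of the
#' test split.
#'
#' @param network A [ddi_network()].
#' @param drug_split Named split vector as in [split_links()].
#' @param link_split Character vector from [split_links()] giving each
#'   labeled pair's split (used to count positives per split).
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed.
#' @return Data frame with columns `i`, `j`, `y` (all 0) and `split`; the
#'   attribute `shortfall` names splits where fewer non-edges existed than
#'   requested.
#' @export
sample_negative_links <- function(network, drug_split, link_split,
                                  ratio = 1, seed = 1L) {
  stopifnot(ratio > 0)
  lp <- network$labeled_pairs
  out <- list()
  shortfall <- integer(0)
  for (k in seq_along(c("train", "valid", "test"))) {
    split <- c("train", "valid", "test")[k]
    n_pos <- sum(lp$y == 1L & link_split == split)
    want <- round(ratio * n_pos)
    cand <- .negative_candidates(network, drug_split, split)
    if (want > nrow(cand)) {
      shortfall[split] <- want - nrow(cand)
      want <- nrow(cand)
    }
    take <- if (want > 0L) {
      withr::with_seed(seed + k, sample.int(nrow(cand), want))
    } else integer(0)
    if (length(take)) {
      out[[split]] <- data.frame(i = cand$i[take], j = cand$j[take],
                                 y = 0L, split = split)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(0), j = integer(0), y = integer(0),
               split = character(0))
  rownames(res) <- NULL
  attr(res, "shortfall") <- shortfall
  res
}
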