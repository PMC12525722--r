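# Molecule parsing, scaffolds, and scaffold-based splitting.

test_that("parse_smiles builds correct graphs and flags bad input", {
  g <- parse_smiles("C")
  expect_true(is_mol_graph(g))
  expect_equal(g$n_atoms, 1L)
  expect_equal(nrow(g$bonds), 0L)

  # heavy-atom and bond counts for ethanol, with an independent count from
  # the SMILES string itself as oracle (3 heavy atoms in a chain = 2 bonds)
  g2 <- parse_smiles("CCO")
  expect_equal(g2$n_atoms, 3L)
  expect_equal(nrow(g2$bonds), 2L)
  expect_equal(sort(g2$element), c("C", "C", "O"))
  expect_true(all(g2$bonds$i < g2$bonds$j))
  expect_true(all(g2$bonds$j <= g2$n_atoms))

  expect_false(is_mol_graph(parse_smiles("not_a_smiles")))
  expect_false(is_mol_graph(parse_smiles("%%")))
  expect_s3_class(parse_smiles("%%"), "smiles_parse_failure")

  # determinism
  ga <- parse_smiles("c1ccncc1")
  gb <- parse_smiles("c1ccncc1")
  expect_identical(ga[c("atom_type", "bonds")], gb[c("atom_type", "bonds")])
})

test_that("parsing a canonical round-trip preserves the graph", {
  for (s in c("CCO", "c1ccccc1", "CC(C)Cc1ccc(C)cc1", "C1CCNCC1")) {
    g <- parse_smiles(s)
    canon <- mvddi:::.mol_canonical_smiles(g)
    g2 <- parse_smiles(canon)
    expect_true(is_mol_graph(g2))
    expect_equal(sort(g2$element), sort(g$element))
    expect_equal(nrow(g2$bonds), nrow(g$bonds))
    # degree multisets are a relabeling invariant
    deg <- function(g) sort(tabulate(c(g$bonds$i, g$bonds$j), g$n_atoms))
    expect_equal(deg(g2), deg(g))
  }
})

test_that("filter_parseable keeps order and reports dropped ids", {
  recs <- data.frame(drug_id = c("d1", "d2", "d3"),
                     smiles = c("CCO", "%%", "c1ccccc1"))
  fp <- filter_parseable(recs)
  expect_equal(fp$kept$drug_id, c("d1", "d3"))
  expect_equal(fp$dropped, "d2")
  expect_true(all(vapply(fp$kept$graph, is_mol_graph, logical(1))))

  all_ok <- filter_parseable(data.frame(drug_id = "a", smiles = "CC"))
  expect_length(all_ok$dropped, 0)
  all_bad <- filter_parseable(data.frame(drug_id = "a", smiles = "%%"))
  expect_equal(nrow(all_bad$kept), 0L)
})

test_that("Bemis-Murcko scaffolds: ring systems and linkers survive, side chains do not", {
  expect_equal(bemis_murcko_scaffold("c1ccccc1"), "c1ccccc1")
  expect_equal(bemis_murcko_scaffold("CCO"), "")
  expect_equal(bemis_murcko_scaffold("C"), "")
  # substituents never change the scaffold
  benzene <- bemis_murcko_scaffold("c1ccccc1")
  expect_equal(bemis_murcko_scaffold("CCc1ccccc1"), benzene)
  expect_equal(bemis_murcko_scaffold("Clc1ccccc1"), benzene)
  # a linker between two rings is part of the scaffold
  bibenzyl <- bemis_murcko_scaffold("c1ccc(CCc2ccccc2)cc1")
  expect_true(nchar(bibenzyl) > nchar(benzene))
  expect_equal(bemis_murcko_scaffold("Cc1ccc(CCc2ccccc2)cc1"), bibenzyl)
  # failure value propagates
  expect_s3_class(bemis_murcko_scaffold("%%"), "smiles_parse_failure")
})

test_that("scaffold membership agrees with an independent cheminformatics toolkit", {
  # RDKit (via the system python) computes Murcko scaffolds independently;
  # its canonical strings are normalized through the same canonicalizer we
  # use so only the structures are compared
  cases <- c("CCc1ccccc1", "CC(=O)c1ccccc1", "C1CCNCC1CC", "Cc1ccncc1",
             "c1ccc(CCc2ccccc2)cc1", "CC(C)Cc1ccc(C)cc1", "O=C1CCCCC1")
  script <- withr::local_tempfile(lines = c(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    "for s in sys.argv[1:]:",
    "    print(MurckoScaffold.MurckoScaffoldSmiles(s))"),
    fileext = ".py")
  out <- suppressWarnings(
    system2("python", c(script, shQuote(cases)), stdout = TRUE,
            stderr = FALSE))
  expect_length(out, length(cases))
  canon <- function(s) {
    if (s == "") return("")
    g <- parse_smiles(s)
    mvddi:::.mol_canonical_smiles(g)
  }
  for (k in seq_along(cases)) {
    expect_equal(bemis_murcko_scaffold(cases[k]), canon(out[k]),
                 label = cases[k])
  }
})

test_that("scaffold_split assigns whole groups at the target ratios", {
  # ten drugs with ten distinct scaffolds split exactly 8:1:1
  drugs <- data.frame(
    drug_id = sprintf("d%02d", 1:10),
    smiles = paste0("CC", c("c1ccccc1", "c1ccncc1", "c1cncnc1", "C1CCCCC1",
                            "C1CCNCC1", "C1CCOCC1", "C1CCCC1", "C1CCOC1",
                            "c1ccc2ccccc2c1", "c1ccoc1")))
  sp <- scaffold_split(drugs, seed = 3)
  expect_equal(as.vector(table(factor(sp$drug_split,
                                      c("train", "valid", "test")))),
               c(8L, 1L, 1L))

  # one shared scaffold cannot be split: everything lands in train
  mono <- data.frame(drug_id = c("a", "b", "c", "d"),
                     smiles = c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
                                "Clc1ccccc1"))
  spm <- scaffold_split(mono, seed = 1)
  expect_true(all(spm$drug_split == "train"))
  expect_true(spm$flags$empty_valid && spm$flags$empty_test)

  # determinism per seed
  expect_identical(scaffold_split(drugs, seed = 7)$drug_split,
                   scaffold_split(drugs, seed = 7)$drug_split)
})

test_that("no scaffold straddles splits and splits partition the drugs", {
  spec <- synthetic_spec(n_drugs = 40, seed = 5)
  drugs <- generate_molecules(spec)
  drugs$scaffold <- vapply(drugs$smiles, bemis_murcko_scaffold, character(1))
  for (seed in 1:10) {
    sp <- scaffold_split(drugs, seed = seed)
    expect_setequal(names(sp$drug_split), drugs$drug_id)
    by_scaffold <- split(sp$drug_split, drugs$scaffold)
    expect_true(all(vapply(by_scaffold,
                           function(v) length(unique(v)) == 1L, logical(1))))
  }
})

test_that("split_links follows the endpoint-inheritance rule exhaustively", {
  net <- toy_network(6, edges = data.frame(
    drug_id_1 = sprintf("T%02d", utils::combn(6, 2)[1, ]),
    drug_id_2 = sprintf("T%02d", utils::combn(6, 2)[2, ])))
  ds <- stats::setNames(c("train", "train", "train", "valid", "test", "test"),
                        sprintf("T%02d", 1:6))
  got <- split_links(net, ds)
  # brute-force application of the rule over all 15 pairs
  want <- apply(utils::combn(6, 2), 2, function(p) {
    s <- ds[sprintf("T%02d", p)]
    if (any(s == "test")) "test" else if (any(s == "valid")) "valid"
    else "train"
  })
  expect_equal(got, unname(want))
  expect_error(split_links(net, ds[-1]), "missing")
})

test_that("negative sampling avoids positives and respects split eligibility", {
  # complete graph: no negatives to sample, shortfall reported
  n <- 5
  all_pairs <- utils::combn(n, 2)
  net <- ddi_network(sprintf("T%02d", 1:n), data.frame(
    drug_id_1 = sprintf("T%02d", all_pairs[1, ]),
    drug_id_2 = sprintf("T%02d", all_pairs[2, ])))
  ds <- stats::setNames(rep("train", n), net$drug_ids)
  ls <- split_links(net, ds)
  neg <- sample_negative_links(net, ds, ls, seed = 1)
  expect_equal(nrow(neg), 0L)
  expect_gt(attr(neg, "shortfall")[["train"]], 0)

  # 4 drugs, 1 positive, ratio 1: exactly one negative, not the positive
  net1 <- ddi_network(letters[1:4],
                      data.frame(drug_id_1 = "a", drug_id_2 = "b"))
  ds1 <- stats::setNames(rep("train", 4), letters[1:4])
  ls1 <- split_links(net1, ds1)
  neg1 <- sample_negative_links(net1, ds1, ls1, seed = 2)
  expect_equal(nrow(neg1), 1L)
  expect_false(neg1$i[1] == 1 && neg1$j[1] == 2)

  # random 20-drug network: negatives disjoint from edges, split-eligible,
  # across many seeds
  ids <- sprintf("R%02d", 1:20)
  pairs20 <- utils::combn(20, 2)
  keep <- withr::with_seed(11, stats::runif(ncol(pairs20)) < 0.2)
  net20 <- ddi_network(ids, data.frame(drug_id_1 = ids[pairs20[1, keep]],
                                       drug_id_2 = ids[pairs20[2, keep]]))
  ds20 <- stats::setNames(rep(c("train", "valid", "test"), c(14, 3, 3)), ids)
  ls20 <- split_links(net20, ds20)
  pos_key <- paste(net20$labeled_pairs$i, net20$labeled_pairs$j)
  for (seed in 1:20) {
    ng <- sample_negative_links(net20, ds20, ls20, seed = seed)
    expect_false(any(paste(ng$i, ng$j) %in% pos_key))
    expect_true(all(ng$i < ng$j))
    lev <- ds20[ids[ng$i]]
    lev2 <- ds20[ids[ng$j]]
    expect_true(all(ifelse(lev == "test" | lev2 == "test", "test",
                           ifelse(lev == "valid" | lev2 == "valid",
                                  "valid", "train")) == ng$split))
  }
})
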