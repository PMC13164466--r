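test_that("tokenizer splits SMILES into indivisible atoms and round-trips", {
  expect_identical(tokenize("C=O"), c("C", "=", "O"))
  expect_identical(tokenize("[C@@]C"), c("[C@@]", "C"))
  expect_identical(tokenize("OCC1CC1Cl"),
                   c("O", "C", "C", "1", "C", "C", "1", "Cl"))
  expect_identical(tokenize("BrCC(=O)N"),
                   c("Br", "C", "C", "(", "=", "O", ")", "N"))
  for (s in c("C=O", "OCC1CC1Cl", "N(C)C", "[C@]1CC1S", "ClC(Br)=O")) {
    expect_identical(paste(tokenize(s), collapse = ""), s)
  }
})

test_that("tokenizer rejects malformed input with the offending position", {
  expect_error(tokenize(""), "empty")
  expect_error(tokenize("[C@@C"), "unbalanced '\\[' at position 1")
  expect_error(tokenize("CC]"), "unbalanced '\\]' at position 3")
  expect_error(tokenize("C(C"), "unbalanced '\\('")
  expect_error(tokenize("CC)O"), "unbalanced '\\)' at position 3")
})

test_that("S_k and SS_k attribute multisets match the worked examples", {
  toks <- tokenize("C=O")
  sk <- sk_attributes(toks)
  expect_identical(sort(names(sk)),
                   sort(sk_code(c("C", "=", "O"))))
  expect_true(all(sk == 1L))

  ssk <- ssk_attributes(toks)
  expect_identical(sort(names(ssk)),
                   sort(c(ssk_code("C", "="), ssk_code("=", "O"))))

  expect_identical(sk_attributes("C"), structure(1L, names = sk_code("C")))
  expect_identical(unname(sk_attributes(c("C", "C", "O"))[sk_code("C")]), 2L)
  expect_length(ssk_attributes("C"), 0L)

  nc <- ssk_attributes(c("N", "(", "C"))
  expect_identical(sort(names(nc)),
                   sort(c(ssk_code("N", "("), ssk_code("(", "C"))))
  expect_identical(ssk_code("N", "("), "N...(.......")
})

test_that("canonical codes are 12 characters wide, dot padded", {
  expect_identical(sk_code("="), "=...........")
  expect_identical(sk_code("[C@@]"), "[C@@].......")
  expect_identical(sk_code("3"), "3...........")
  expect_identical(ssk_code("=", "("), "=...(.......")
  expect_identical(ssk_code("O", "2"), "O...2.......")
  expect_identical(nnc_key("C", 321L), "NNC-C...321.")
  expect_identical(nnc_key("O", 110L), "NNC-O...110.")
  expect_identical(nnc_key("N", 0L), "NNC-N...000.")
})

test_that("graph construction follows chain, branch and ring semantics", {
  g <- build_graph("C=O")
  expect_identical(g$vertices$element, c("C", "O"))
  expect_identical(nrow(g$edges), 1L)

  tri <- build_graph("C1CC1")
  expect_identical(nrow(tri$vertices), 3L)
  expect_identical(nrow(tri$edges), 3L)

  single <- build_graph("O")
  expect_identical(nrow(single$vertices), 1L)
  expect_identical(nrow(single$edges), 0L)

  branched <- build_graph("CC(=O)N")
  expect_identical(branched$vertices$element, c("C", "C", "O", "N"))
  # edges: C1-C2, C2-O, C2-N
  expect_identical(nrow(branched$edges), 3L)
  deg2 <- sum(branched$edges == 2L)
  expect_identical(deg2, 3L)

  stereo <- build_graph("[C@@]C")
  expect_identical(stereo$vertices$element, c("C", "C"))

  expect_error(build_graph("C1CC"), "unmatched ring-closure")
  expect_error(build_graph("CC="), "dangling bond")
})

test_that("nearest neighbor codes follow 100*NT + 10*NC + NX", {
  expect_identical(nnc_code(3L, 2L, 1L), 321L)
  expect_identical(nnc_code(2L, 2L, 0L), 220L)
  expect_identical(nnc_code(0L, 0L, 0L), 0L)
  expect_identical(nnc_code(4L, 4L, 0L), 440L)
  expect_error(nnc_code(3L, 1L, 1L), "invariant")
  expect_error(nnc_code(-1L, 0L, -1L), "non-negative")
})

test_that("per-vertex NNC attributes count carbon and non-carbon neighbors", {
  eth <- nnc_attributes(build_graph("CCO"))
  expect_identical(unname(eth[c("NNC-C...110.", "NNC-C...211.",
                                "NNC-O...110.")]), rep(1L, 3L))
  fa <- nnc_attributes(build_graph("C=O"))
  expect_identical(sort(names(fa)), c("NNC-C...101.", "NNC-O...110."))
  lone <- nnc_attributes(build_graph("S"))
  expect_identical(names(lone), "NNC-S...000.")
})

test_that("featurize is the multiset union of the three families", {
  ms <- featurize("C=O")
  expect_identical(sum(ms), 7L)  # 3 S_k + 2 SS_k + 2 NNC instances
  expect_length(ms, 7L)

  lone <- featurize("C")
  expect_identical(sort(names(lone)), sort(c(sk_code("C"), "NNC-C...000.")))

  expect_identical(featurize("C=O"), featurize("C=O"))
  expect_identical(featurize("  C=O \n"), featurize("C=O"))
})

test_that("graph invariants hold over a generated corpus", {
  smiles <- gen_smiles(generator_config(n_compounds = 150L, seed = 7L))
  for (s in smiles) {
    toks <- tokenize(s)
    expect_identical(paste(toks, collapse = ""), s)
    g <- build_graph(s)
    deg <- tabulate(c(g$edges), nbins = nrow(g$vertices))
    el <- g$vertices$element
    for (v in seq_len(nrow(g$vertices))) {
      nb <- c(g$edges[g$edges[, 1] == v, 2], g$edges[g$edges[, 2] == v, 1])
      expect_identical(sum(el[nb] == "C") + sum(el[nb] != "C"), deg[v])
    }
    expect_identical(sum(deg), 2L * nrow(g$edges))
    # vertex count equals number of atom tokens
    n_atoms <- sum(grepl("^\\[", toks) |
                     toks %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                                 "b", "c", "n", "o", "p", "s", "Cl", "Br"))
    expect_identical(nrow(g$vertices), n_atoms)
  }
})
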