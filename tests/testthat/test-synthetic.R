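test_that("a toy complex realizes exactly its designed contact set", {
  spec <- ensemble_spec(
    n_models = 1, chains = c(A = 10, B = 10),
    conserved_contacts = list(c("A:2", "B:2"), c("A:5", "B:5"),
                              c("A:7", "B:9"), c("A:10", "B:10")),
    seed = 4)
  toy <- make_toy_complex(spec)
  cm <- contact_maps(toy)
  got <- sort(paste(res_id(cm$chain1, cm$resseq1, cm$icode1),
                    res_id(cm$chain2, cm$resseq2, cm$icode2)))
  expect_equal(got, sort(c("A:2 B:2", "A:5 B:5", "A:7 B:9", "A:10 B:10")))
  ## agreement with the brute-force oracle too
  expect_identical(contact_keys(cm), brute_contact_map(toy))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- ensemble_spec(chains = c(A = 5, B = 5),
                        conserved_contacts = list(c("A:1", "B:1")),
                        seed = 11)
  expect_identical(make_toy_complex(spec), make_toy_complex(spec))
  e1 <- make_perturbed_ensembles(spec)
  e2 <- make_perturbed_ensembles(spec)
  expect_identical(e1$wt, e2$wt)
  expect_identical(e1$mut, e2$mut)
  ## zero jitter is exactly the designed lattice
  spec0 <- ensemble_spec(chains = c(A = 5, B = 5), jitter_sd = 0, seed = 11)
  expect_identical(make_toy_complex(spec0), make_toy_complex(spec0))
})

test_that("a single-residue model has an empty contact map", {
  spec <- ensemble_spec(n_models = 1, chains = c(A = 1), seed = 1)
  expect_equal(nrow(contact_maps(make_toy_complex(spec))), 0)
})

test_that("designed perturbations surface as exact delta = m/n", {
  spec <- ensemble_spec(
    n_models = 20, chains = c(A = 8, B = 8),
    conserved_contacts = list(c("A:2", "B:2")),
    perturbed_pairs = tibble::tibble(res1 = c("A:4", "A:6", "A:8"),
                                     res2 = c("B:4", "B:6", "B:8"),
                                     m = c(9, 0, 20)),
    seed = 13, mutation_site = "B:5")
  ens <- make_perturbed_ensembles(spec)
  d <- difference_map(
    contact_frequency(contact_maps(ens$wt), 20),
    contact_frequency(contact_maps(ens$mut), 20))
  td <- tidy(d)
  expect_equal(td$delta[td$res1 == "A:4"], 9 / 20)
  expect_equal(td$delta[td$res1 == "A:6"], 0)     # m = 0: unchanged
  expect_equal(td$delta[td$res1 == "A:8"], 1)     # m = 20: fully broken
  expect_equal(td$delta[td$res1 == "A:2"], 0)     # conserved contact
  ## no contact changes anywhere else (zero false positives)
  expect_true(all(td$delta[!td$res1 %in% c("A:4", "A:8")] == 0))
  ## mutant models carry the mutated residue name at shared numbering
  expect_equal(unique(ens$wt$resname[ens$wt$chain == "B" &
                                       ens$wt$resseq == 5]), "ARG")
  expect_equal(unique(ens$mut$resname[ens$mut$chain == "B" &
                                        ens$mut$resseq == 5]), "HIS")
})

test_that("unrealizable or inconsistent specs fail before generation", {
  expect_error(ensemble_spec(chains = c(A = 5, B = 5),
                             conserved_contacts = list(c("A:1", "B:5"))),
               NA)  # any anchor works: moved residue relocates
  expect_error(
    ensemble_spec(chains = c(A = 5, B = 5),
                  conserved_contacts = list(c("A:1", "B:2"),
                                            c("A:3", "B:2"))),
    "only one pair")
  expect_error(
    ensemble_spec(chains = c(A = 5, B = 5),
                  conserved_contacts = list(c("A:1", "B:2"),
                                            c("B:2", "A:4"))),
    "may not anchor")
  expect_error(
    ensemble_spec(chains = c(A = 5), conserved_contacts = list(c("A:1", "C:9"))),
    "unknown residue")
  expect_error(
    ensemble_spec(n_models = 10,
                  perturbed_pairs = tibble::tibble(res1 = "A:1", res2 = "B:1",
                                                   m = 11)),
    "n_models")
})

test_that("score tables honour their construction modes", {
  dt <- make_score_table(1000, "disjoint-tops")
  top_a <- dt$model_id[order(dt$score_a)][1:10]
  top_b <- dt$model_id[order(dt$score_b)][1:10]
  expect_length(intersect(top_a, top_b), 0)
  expect_equal(nrow(select_models(dt, k = 10)), 20)

  idt <- make_score_table(100, "identical")
  expect_identical(idt$score_a, idt$score_b)

  r1 <- make_score_table(100, "random", seed = 42)
  expect_identical(r1, make_score_table(100, "random", seed = 42))
  expect_false(identical(r1, make_score_table(100, "random", seed = 43)))
})

test_that("generated ensembles survive a disk round trip unchanged", {
  spec <- ensemble_spec(n_models = 3, chains = c(A = 4, B = 4),
                        conserved_contacts = list(c("A:2", "B:3")),
                        perturbed_pairs = tibble::tibble(
                          res1 = "A:4", res2 = "B:4", m = 2),
                        seed = 17)
  ens <- make_perturbed_ensembles(spec)
  dir <- file.path(tempdir(), "synthetic-rt")
  write_structures(ens$mut, dir)
  back <- suppressMessages(read_structures(file.path(dir, "*.pdb")))
  expect_identical(contact_keys(contact_maps(back)),
                   contact_keys(contact_maps(ens$mut)))
})
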