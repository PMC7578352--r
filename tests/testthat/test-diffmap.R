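make_diff <- function(counts_wt, counts_mut, n = 20, threshold = 0.4) {
  difference_map(freq_from_counts(counts_wt, n, "wt"),
                 freq_from_counts(counts_mut, n, "mut"),
                 threshold = threshold)
}

test_that("identical ensembles give an all-zero, unannotated map", {
  counts <- tibble::tibble(res1 = c("A:1", "A:3"), res2 = c("B:1", "B:9"),
                           k = c(20, 13))
  d <- make_diff(counts, counts)
  expect_true(all(d$delta == 0))
  expect_equal(nrow(annotate_differences(d)), 0)
  expect_equal(suppressWarnings(net_contact_change(d)), 0)
})

test_that("delta is WT minus mutant: loss is positive, gain negative", {
  d <- make_diff(tibble::tibble(res1 = "A:1", res2 = "B:1", k = 20),
                 tibble::tibble(res1 = c("A:1", "A:2"),
                                res2 = c("B:1", "B:2"), k = c(11, 20)))
  td <- tidy(d)
  expect_equal(td$delta[td$res1 == "A:1"], 0.45)   # 1.00 - 0.55 = loss
  expect_equal(td$delta[td$res1 == "A:2"], -1)     # absent in WT = gain
  ann <- annotate_differences(d)
  expect_equal(ann$direction[ann$chain1 == "A" & ann$resseq1 == 2], "gain")
  expect_equal(ann$direction[ann$chain1 == "A" & ann$resseq1 == 1], "loss")
})

test_that("difference maps are antisymmetric in their arguments", {
  a <- tibble::tibble(res1 = c("A:1", "A:2", "A:5"),
                      res2 = c("B:1", "B:2", "B:5"), k = c(20, 7, 0))
  b <- tibble::tibble(res1 = c("A:1", "A:2", "A:5"),
                      res2 = c("B:1", "B:2", "B:5"), k = c(3, 19, 14))
  dab <- make_diff(a, b)
  dba <- make_diff(b, a)
  expect_equal(tidy(dab)$delta, -tidy(dba)$delta)
  expect_equal(net_contact_change(dab), -net_contact_change(dba))
})

test_that("annotation threshold is strict: 8 of 20 silent, 9 of 20 annotated", {
  for (k_discord in c(8, 9)) {
    d <- make_diff(tibble::tibble(res1 = "A:1", res2 = "B:1", k = 20),
                   tibble::tibble(res1 = "A:1", res2 = "B:1",
                                  k = 20 - k_discord))
    ann <- annotate_differences(d)
    if (k_discord == 8) {
      expect_equal(tidy(d)$delta, 0.4)
      expect_equal(nrow(ann), 0)      # exactly at 40%: not annotated
    } else {
      expect_equal(tidy(d)$delta, 0.45)
      expect_equal(nrow(ann), 1)      # more than 40%: annotated
    }
  }
})

test_that("annotated pairs sort by |delta| descending with stable pair ties", {
  d <- make_diff(
    tibble::tibble(res1 = c("A:1", "A:2", "A:3"),
                   res2 = c("B:1", "B:2", "B:3"), k = c(20, 20, 20)),
    tibble::tibble(res1 = c("A:1", "A:2", "A:3"),
                   res2 = c("B:1", "B:2", "B:3"), k = c(10, 2, 10)))
  ann <- annotate_differences(d)
  expect_equal(ann$resseq1, c(2, 1, 3))
  expect_equal(abs(ann$delta), sort(abs(ann$delta), decreasing = TRUE))
})

test_that("net change equals the difference of mean per-model contact counts", {
  spec <- ensemble_spec(n_models = 20, chains = c(A = 8, B = 8),
                        conserved_contacts = list(c("A:2", "B:2"),
                                                  c("A:6", "B:7")),
                        perturbed_pairs = tibble::tibble(
                          res1 = c("A:4", "A:8"), res2 = c("B:4", "B:8"),
                          m = c(9, 15)),
                        seed = 21)
  ens <- make_perturbed_ensembles(spec)
  cm_wt <- contact_maps(ens$wt)
  cm_mut <- contact_maps(ens$mut)
  d <- difference_map(contact_frequency(cm_wt, 20),
                      contact_frequency(cm_mut, 20))
  mean_wt <- nrow(cm_wt) / 20
  mean_mut <- nrow(cm_mut) / 20
  expect_equal(net_contact_change(d, "all"), mean_wt - mean_mut,
               tolerance = 1e-12)
  expect_equal(net_contact_change(d, "all"), (9 + 15) / 20)
})

test_that("region-restricted net change and empty selections behave", {
  d <- make_diff(tibble::tibble(res1 = c("A:1", "A:2"),
                                res2 = c("B:1", "A:5"), k = c(20, 20)),
                 tibble::tibble(res1 = c("A:1", "A:2"),
                                res2 = c("B:1", "A:5"), k = c(0, 10)))
  expect_equal(net_contact_change(d, chains = c("A", "B")), 1)
  expect_warning(out <- net_contact_change(d, chains = c("A", "C")),
                 "Empty")
  expect_equal(out, 0)
})

test_that("mismatched contact parameters or residue universes are errors", {
  cm1 <- contact_maps(two_atom_system(4.0))
  cm2 <- contact_maps(two_atom_system(4.0), contact_params(cutoff = 5))
  f1 <- contact_frequency(cm1, 1)
  f2 <- contact_frequency(cm2, 1)
  expect_error(difference_map(f1, f2), "different contact parameters")

  sys1 <- two_atom_system(4.0)
  sys2 <- dplyr::mutate(sys1, resseq = resseq + 1L)
  g1 <- contact_frequency(cm1, 1, residue_keys = residue_keys(sys1))
  g2 <- contact_frequency(contact_maps(sys2), 1,
                          residue_keys = residue_keys(sys2))
  expect_error(difference_map(g1, g2), "universes differ")
})

test_that("glance summarizes a difference map consistently with its parts", {
  d <- make_diff(tibble::tibble(res1 = c("A:1", "A:2"),
                                res2 = c("B:1", "B:2"), k = c(20, 20)),
                 tibble::tibble(res1 = c("A:1", "A:2"),
                                res2 = c("B:1", "B:2"), k = c(0, 15)))
  g <- glance(d)
  expect_equal(g$n_pairs, 2)
  expect_equal(g$n_annotated, 1)
  expect_equal(g$net_all, 1.25)
  expect_equal(g$net_annotated, 1)
  expect_equal(g$threshold, 0.4)
})

test_that("RWB colors interpolate linearly between the three anchors", {
  cols <- delta_color(c(1, 0, -1, 0.5, -0.25))
  expect_equal(unname(as.matrix(cols)[1, ]), c(1, 0, 0))   # full loss: red
  expect_equal(unname(as.matrix(cols)[2, ]), c(1, 1, 1))   # no change: white
  expect_equal(unname(as.matrix(cols)[3, ]), c(0, 0, 1))   # full gain: blue
  expect_equal(unname(as.matrix(cols)[4, ]), c(1, 0.5, 0.5))
  expect_equal(unname(as.matrix(cols)[5, ]), c(0.75, 0.75, 1))
  expect_error(delta_color(1.5), "\\[-1, 1\\]")
})

test_that("beads sit at the midpoint of heavy-atom centroids", {
  ref <- dplyr::bind_rows(
    atom_row(chain = "A", resseq = 1, x = 0, y = 0, z = 0),
    atom_row(chain = "A", resseq = 1, atom = "CB", x = 0, y = 2, z = 0),
    atom_row(chain = "A", resseq = 1, atom = "HA", element = "H",
             x = 50, y = 50, z = 50),            # hydrogens never count
    atom_row(chain = "B", resseq = 1, x = 2, y = 1, z = 0))
  pairs <- tibble::tibble(chain1 = "A", resseq1 = 1L, icode1 = "",
                          chain2 = "B", resseq2 = 1L, icode2 = "",
                          delta = 0.5)
  bead <- bead_geometry(pairs, ref)
  expect_equal(c(bead$x, bead$y, bead$z), c(1, 1, 0))
  expect_equal(c(bead$r, bead$g, bead$b), c(1, 0.5, 0.5))
  missing <- dplyr::mutate(pairs, resseq2 = 9L)
  expect_error(bead_geometry(missing, ref), "absent from reference")
})
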