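test_that("moment IBD recovers duplicate, parent-offspring and unrelated pairs", {
  st <- shared_study()
  d <- st$genotypes$dosages
  f <- st$freqs
  dup <- moment_ibd(d[1, ], d[1, ], f)
  expect_gt(dup["ibd2"], 0.95)
  expect_equal(unname(dup["kinship_hat"]), 0.5, tolerance = 0.02)

  # F001_I03 is a child of F001_I01 x F001_I02
  po <- moment_ibd(d["F001_I01", ], d["F001_I03", ], f)
  expect_lt(po["ibd0"], 0.05)
  expect_lt(abs(po["ibd1"] - 1), 0.1)
  expect_lt(abs(po["kinship_hat"] - 0.25), 0.03)

  un <- moment_ibd(d["F001_I01", ], d["F002_I01", ], f)
  expect_lt(abs(un["kinship_hat"]), 0.03)
  expect_equal(sum(po[1:3]), 1)
})

test_that("vectorized pair scan matches the single-pair estimator", {
  st <- shared_study()
  ids <- rownames(st$genotypes$dosages)
  pairs <- data.frame(id1 = ids[c(1, 1, 5)], id2 = ids[c(2, 3, 40)])
  tab <- ibd_estimates(st$genotypes, st$freqs, pairs = pairs)
  for (r in seq_len(nrow(pairs))) {
    one <- moment_ibd(st$genotypes$dosages[pairs$id1[r], ],
                      st$genotypes$dosages[pairs$id2[r], ], st$freqs)
    expect_equal(unlist(tab[r, c("ibd0", "ibd1", "ibd2", "kinship_hat")]),
                 one, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("relationship classification uses the kinship bands and ibd0 split", {
  expect_equal(classify_relationship(0.02, 0.96, 0.02, 0.25), "parent-offspring")
  expect_equal(classify_relationship(0.25, 0.50, 0.25, 0.25), "full-sibling")
  expect_equal(classify_relationship(1, 0, 0, 0), "unrelated")
  expect_equal(classify_relationship(0, 0, 1, 0.5), "MZ/duplicate")
  expect_equal(classify_relationship(0.5, 0.5, 0, 0.125), "2nd-degree")
  # monotone: increasing kinship_hat never moves the call away from MZ
  rank_of <- c("unrelated" = 1, "3rd-degree" = 2, "2nd-degree" = 3,
               "parent-offspring" = 4, "full-sibling" = 4, "MZ/duplicate" = 5)
  kh <- seq(0, 0.5, by = 0.005)
  cls <- classify_relationship(rep(0, length(kh)), rep(0, length(kh)),
                               rep(0, length(kh)), kh)
  expect_true(all(diff(rank_of[cls]) >= 0))
})

test_that("named genealogical relationships are recovered from the graph", {
  ped <- pedigree(rep("f", 8),
                  c("gf", "gm", "a", "b", "as", "bs", "ca", "cb"),
                  c(NA, NA, "gf", "gf", NA, NA, "as", "bs"),
                  c(NA, NA, "gm", "gm", NA, NA, "a", "b"),
                  c("male", "female", "female", "female", "male", "male",
                    "male", "male"))
  expect_equal(relationship_name(ped, "gf", "a"), "parent-offspring")
  expect_equal(relationship_name(ped, "a", "b"), "full-sibling")
  expect_equal(relationship_name(ped, "a", "cb"), "avuncular")
  expect_equal(relationship_name(ped, "gf", "ca"), "grandparent-grandchild")
  expect_equal(relationship_name(ped, "ca", "cb"), "first-cousin")
})

test_that("expected avuncular inferred as parent-offspring is discordant", {
  st <- shared_study()
  calls <- relationship_calls(st$ped, st$genotypes, st$freqs)
  w <- calls[calls$expected_class != "cross-pedigree", ]
  # an intact simulated study: concordance is high
  expect_gt(mean(!w$discordant), 0.95)
  # doctor one avuncular pair to look parent-offspring
  av <- which(w$expected_name == "avuncular")[1]
  w$ibd0[av] <- 0.02; w$ibd1[av] <- 0.96; w$ibd2[av] <- 0.02
  w$kinship_hat[av] <- 0.25
  w$inferred_class[av] <- classify_relationship(0.02, 0.96, 0.02, 0.25)
  w$discordant[av] <- w$inferred_class[av] != w$expected_class[av]
  expect_true(w$discordant[av])
  rep <- pedigree_discordance(st$ped, w)
  expect_true(all(c(w$id1[av], w$id2[av]) %in%
                    c(rep$discordant_pairs$id1, rep$discordant_pairs$id2)))
  # a concordant full-sib pair is not reported
  fs <- w[w$expected_name == "full-sibling" & !w$discordant, ][1, ]
  expect_false(any(rep$discordant_pairs$id1 == fs$id1 &
                     rep$discordant_pairs$id2 == fs$id2))
})

test_that("a planted sample swap is proposed for exclusion, and only it", {
  cfg <- sim_config(n_families = 12, n_snps = 4000, true_h2 = 0.4, seed = 3,
                    planted_swap = c("F001_I03", "F005_I03"))
  st <- simulate_study(cfg)
  calls <- relationship_calls(st$ped, st$genotypes, st$freqs)
  rep <- pedigree_discordance(st$ped, calls)
  expect_setequal(rep$proposed_exclusions, cfg$planted_swap)
  # swapped samples also surface as elevated cross-pedigree kinship
  expect_true(any(rep$cross_pedigree$id1 %in% cfg$planted_swap |
                    rep$cross_pedigree$id2 %in% cfg$planted_swap))
})
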