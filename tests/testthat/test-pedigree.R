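test_that("trio parses from both dialects and founders are identified", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("fam1 F 0 0 1", "fam1 M 0 0 2", "fam1 C F M 2"), f)
  ped <- read_pedigree(f, dialect = "linkage")
  expect_s3_class(ped, "kin_pedigree")
  expect_equal(sum(ped$founder), 2)
  expect_equal(ped$id[!ped$founder], "C")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("famid,id,fa,mo,sex", "fam1,F,0,0,male", "fam1,M,0,0,female",
               "fam1,C,F,M,female"), g)
  expect_equal(read_pedigree(g, dialect = "solar-csv")$founder, ped$founder)
})

test_that("validation failures raise distinct named errors", {
  expect_error(pedigree(c("f", "f"), c("A", "A"), c(NA, NA), c(NA, NA),
                        c("male", "male")),
               class = "kinherit_duplicate_id_error")
  # individual listing itself as father
  expect_error(pedigree("f", "C", "C", "M", "male"),
               class = "kinherit_missing_parent_error")
  expect_error(pedigree(c("f", "f"), c("C", "M"), c("C", NA), c("M", NA),
                        c("male", "female")),
               class = "kinherit_cycle_error")
  # two-generation cycle: A's father is B, B's father is A
  expect_error(pedigree(c("f", "f", "f"), c("A", "B", "M"),
                        c("B", "A", NA), c("M", "M", NA),
                        c("male", "male", "female")),
               class = "kinherit_cycle_error")
  expect_error(pedigree(c("f", "f", "f"), c("F", "M", "C"),
                        c(NA, NA, "F"), c(NA, NA, "M"),
                        c("female", "female", "male")),
               class = "kinherit_parent_sex_error")
  expect_error(pedigree(c("f", "f"), c("F", "C"), c(NA, "F"), c(NA, NA),
                        c("male", "male")),
               class = "kinherit_half_parentage_error")
})

test_that("kinship coefficients match Mendelian expectations", {
  # grandparents gf x gm; full sibs a, b; their spouses; first cousins ca, cb
  ped <- pedigree(rep("f", 8),
                  c("gf", "gm", "a", "b", "as", "bs", "ca", "cb"),
                  c(NA, NA, "gf", "gf", NA, NA, "as", "bs"),
                  c(NA, NA, "gm", "gm", NA, NA, "a", "b"),
                  c("male", "female", "female", "female", "male", "male",
                    "male", "male"))
  k <- kin_values(pedigree_kinship(ped))
  expect_equal(k["gf", "a"], 0.5)    # parent-offspring
  expect_equal(k["a", "b"], 0.5)     # full siblings
  expect_equal(k["a", "cb"], 0.25)   # avuncular
  expect_equal(k["ca", "cb"], 0.125) # first cousins
  expect_equal(k["gf", "as"], 0)     # unrelated founders
  expect_equal(diag(k), setNames(rep(1, 8), rownames(k)))

  # child of full-sib mating: F = 0.25, diagonal 1.25
  inb <- pedigree(rep("f", 5), c("gf", "gm", "s1", "s2", "c"),
                  c(NA, NA, "gf", "gf", "s1"), c(NA, NA, "gm", "gm", "s2"),
                  c("male", "female", "male", "female", "female"))
  expect_equal(kin_values(pedigree_kinship(inb))["c", "c"], 1.25)
})

test_that("pedigree kinship is symmetric PSD and zero across families", {
  for (seed in 1:5) {
    ped <- random_pedigree(seed, n_max = 20)
    k <- kin_values(pedigree_kinship(ped))
    expect_equal(k, t(k))
    expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  st <- shared_study()
  k <- kin_values(st$kinship)
  ids <- sample_ids(st$ped)
  cross <- outer(st$ped$fam, st$ped$fam, "!=")
  expect_true(all(k[cross] == 0))
  expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("removing a connecting ancestor never increases relatedness", {
  ped <- pedigree(rep("f", 8),
                  c("gf", "gm", "a", "b", "as", "bs", "ca", "cb"),
                  c(NA, NA, "gf", "gf", NA, NA, "as", "bs"),
                  c(NA, NA, "gm", "gm", NA, NA, "a", "b"),
                  c("male", "female", "female", "female", "male", "male",
                    "male", "male"))
  # sever the grandparental link: a and b become founders
  cut <- pedigree(rep("f", 6), c("a", "b", "as", "bs", "ca", "cb"),
                  c(NA, NA, NA, NA, "as", "bs"),
                  c(NA, NA, NA, NA, "a", "b"),
                  c("female", "female", "male", "male", "male", "male"))
  k1 <- kin_values(pedigree_kinship(ped))
  k2 <- kin_values(pedigree_kinship(cut))
  ids <- rownames(k2)
  off <- upper.tri(k2)
  expect_true(all(k2[off] <= k1[ids, ids][off] + 1e-12))
})

test_that("recursion agrees with Monte-Carlo allele dropping on small pedigrees", {
  for (seed in c(3, 9)) {
    ped <- random_pedigree(seed, n_max = 14)
    k <- kin_values(pedigree_kinship(ped))
    mc <- mc_kinship(ped, n_drops = 5000, seed = seed + 100)
    z <- abs(k - mc$k2) / pmax(mc$se, 1e-12)
    z[mc$se == 0] <- 0
    expect_true(all(abs(k - mc$k2)[mc$se == 0] < 1e-12))
    # ~100 distinct entries per pedigree: allow the expected handful of
    # 3-SE exceedances, none extreme
    expect_gte(mean(z <= 3), 0.97)
    expect_lt(max(z), 5)
  }
})

test_that("simulated pedigrees round-trip through write and read", {
  cfg <- sim_config(n_families = 2, n_children = 2, n_grandchildren = 2,
                    seed = 5)
  ped <- simulate_pedigree(cfg)
  for (dialect in c("linkage", "solar-csv")) {
    f <- withr::local_tempfile()
    write_pedigree(ped, f, dialect = dialect)
    back <- read_pedigree(f, dialect = dialect)
    expect_equal(back$id, ped$id)
    expect_equal(back$fa, ped$fa)
    expect_equal(back$mo, ped$mo)
    expect_equal(back$sex, ped$sex)
    expect_equal(back$founder, ped$founder)
  }
})
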