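# Random incidence matrix with every species detected somewhere.
random_incidence <- function(n_sp, n_st, p = 0.3) {
  m <- matrix(rbinom(n_sp * n_st, 1, p), n_sp, n_st,
              dimnames = list(sprintf("sp%02d", 1:n_sp),
                              sprintf("st%02d", 1:n_st)))
  m[rowSums(m) == 0, sample.int(n_st, 1)] <- 1L
  m
}

test_that("Jackknife-1 richness follows S_obs + f1 (n-1)/n", {
  # 10 species, 4 uniques, 20 stations -> 10 + 4 * 19/20 = 13.8
  m <- matrix(0L, 10, 20)
  m[, 1:2] <- 1L            # all species at two stations
  m[1:4, 2:20] <- 0L        # species 1..4 only at station 1
  j <- jackknife1(m)
  expect_equal(j$S_obs, 10)
  expect_equal(j$f1, 4)
  expect_equal(j$S_jack1, 13.8)
  # no uniques: estimate equals observed
  m2 <- matrix(1L, 5, 6)
  expect_equal(jackknife1(m2)$S_jack1, 5)
  # single station: (n-1)/n = 0
  m3 <- matrix(1L, 5, 1)
  expect_equal(jackknife1(m3)$S_jack1, 5)
  expect_error(jackknife1(matrix(0L, 0, 0)), "empty")
})

test_that("Jackknife-1 equals the leave-one-station-out estimator", {
  # resampling identity: S_obs + (n-1)/n * sum over stations of species
  # lost when that station is dropped
  set.seed(21)
  for (i in 1:10) {
    m <- random_incidence(sample(4:12, 1), sample(3:10, 1))
    n <- ncol(m)
    lost <- vapply(seq_len(n), function(j) {
      sum(rowSums(m) > 0) - sum(rowSums(m[, -j, drop = FALSE]) > 0)
    }, numeric(1))
    loo <- sum(rowSums(m) > 0) + (n - 1) / n * sum(lost)
    expect_equal(jackknife1(m)$S_jack1, loo)
  }
})

test_that("analytic rarefaction matches resampling and is concave nondecreasing", {
  set.seed(31)
  m <- random_incidence(8, 12)
  curve <- rarefaction_curve(m)
  expect_equal(nrow(curve), 12L)
  # final point is the observed richness
  expect_equal(curve$expected_S[12], sum(rowSums(m) > 0))
  # nondecreasing, concave (second differences <= 0)
  expect_true(all(diff(curve$expected_S) >= -1e-12))
  expect_true(all(diff(diff(curve$expected_S)) <= 1e-9))
  # permutation oracle at a few subsample sizes
  perm <- rarefaction_curve(m, h = c(3, 6, 9), method = "resample",
                            n_perm = 10000, seed = 99)
  ana <- rarefaction_curve(m, h = c(3, 6, 9))
  expect_equal(perm$expected_S, ana$expected_S, tolerance = 0.02)
  # one ubiquitous species: curve constant at 1
  m1 <- matrix(1L, 1, 6)
  expect_equal(rarefaction_curve(m1)$expected_S, rep(1, 6))
  expect_error(rarefaction_curve(m, h = 13), "outside")
})

test_that("analytic rarefaction agrees with vegan's exact method", {
  skip_if_not_installed("vegan")
  set.seed(41)
  m <- random_incidence(10, 15)
  ours <- rarefaction_curve(m)$expected_S
  ref <- vegan::specaccum(t(m), method = "exact")$richness
  expect_equal(ours, as.numeric(ref), tolerance = 1e-8)
})

test_that("diversity indices follow the Shannon and Gini-Simpson formulas", {
  # 10 equally abundant species
  d <- diversity_indices(rep(2.5, 10))
  expect_equal(d$H_shannon, log(10))
  expect_equal(d$D_simpson, 0.90)
  # single species
  d1 <- diversity_indices(5)
  expect_equal(d1$H_shannon, 0)
  expect_equal(d1$D_simpson, 0)
  # proportions (0.5, 0.3, 0.2)
  d3 <- diversity_indices(c(0.5, 0.3, 0.2))
  expect_equal(d3$H_shannon, 1.0297, tolerance = 1e-4)
  expect_equal(d3$D_simpson, 0.62)
  # scale invariance
  w <- c(4.05, 3.56, 0.84, 1.2, 0.3)
  expect_equal(diversity_indices(w), diversity_indices(w * 37.5))
  # inverse Simpson option
  expect_equal(diversity_indices(rep(1, 4), simpson = "inverse")$D_simpson, 4)
  expect_error(diversity_indices(c(0, 0)), "all-zero")
  expect_error(diversity_indices(c(-1, 2)), ">= 0")
})

test_that("diversity agrees with vegan on RAI-style weights", {
  skip_if_not_installed("vegan")
  set.seed(51)
  w <- rlnorm(20, 0, 1)
  d <- diversity_indices(w)
  expect_equal(d$H_shannon, unname(vegan::diversity(w, "shannon")))
  expect_equal(d$D_simpson, unname(vegan::diversity(w, "simpson")))
})

test_that("similarity indices count shared and unique species", {
  # 22 shared, 5 unique to one community, 3 to the other
  shared <- sprintf("shared%02d", 1:22)
  ua <- sprintf("only_a%d", 1:5)
  ub <- sprintf("only_b%d", 1:3)
  s <- community_similarity(c(shared, ua), c(shared, ub))
  expect_equal(s$A, 22); expect_equal(s$B, 5); expect_equal(s$C, 3)
  expect_equal(round(s$J, 2), 0.73)
  expect_equal(round(s$CC, 2), 0.85)
  expect_equal(round(100 * s$D_CC), 15)
  # identical and disjoint lists
  id <- community_similarity(shared, shared)
  expect_equal(id$J, 1); expect_equal(id$CC, 1); expect_equal(id$D_CC, 0)
  dj <- community_similarity(ua, ub)
  expect_equal(dj$J, 0); expect_equal(dj$CC, 0); expect_equal(dj$D_CC, 1)
  # case-insensitive matching
  expect_equal(community_similarity(c("Hyrax"), c("hyrax "))$J, 1)
  expect_error(community_similarity(character(0), character(0)),
               "undefined")
})

test_that("J <= CC for random communities (algebraic property)", {
  set.seed(61)
  pool <- sprintf("sp%03d", 1:40)
  for (i in 1:25) {
    s1 <- sample(pool, sample(1:30, 1))
    s2 <- sample(pool, sample(1:30, 1))
    s <- community_similarity(s1, s2)
    expect_lte(s$J, s$CC + 1e-12)
    expect_lte(s$CC, 1)
    expect_equal(s$J, s$A / (s$A + s$B + s$C))
  }
})

test_that("community-structure table joins traits and flags dominance", {
  traits <- data.frame(species = c("hyrax", "duiker", "caracal"),
                       body_mass_kg = c(3.2, 17.5, 11),
                       guild = c("herbivore", "herbivore", "carnivore"))
  mk_rai <- function(raivals) {
    g <- data.frame(species = names(raivals),
                    events = as.integer(raivals * 10),
                    effort_days = 1000, rai = unname(raivals))
    structure(list(by_station = g[0, ], global = g), class = "rai_table")
  }
  tab <- community_structure_table(mk_rai(c(hyrax = 1, duiker = 1,
                                            caracal = 2)), traits)
  expect_equal(tab$share[match(c("hyrax", "duiker", "caracal"),
                               tab$species)], c(0.25, 0.25, 0.50))
  expect_false(any(tab$dominant))  # 50% share is not > 50%
  # sorted by guild then mass
  expect_equal(tab$species, c("caracal", "hyrax", "duiker"))
  tab2 <- community_structure_table(mk_rai(c(hyrax = 6, duiker = 2,
                                             caracal = 2)), traits)
  expect_true(tab2$dominant[tab2$species == "hyrax"])
  expect_error(
    community_structure_table(mk_rai(c(leopard = 1)), traits),
    "leopard")
  empty <- structure(list(by_station = data.frame(),
                          global = data.frame(species = character(0),
                                              events = integer(0),
                                              effort_days = numeric(0),
                                              rai = numeric(0))),
                     class = "rai_table")
  expect_equal(nrow(community_structure_table(empty, traits)), 0L)
})

test_that("incidence matrices respect the blocklist and station set", {
  ev <- deduplicate_events(make_records(
    c("A", "B", "B"), c("hyrax", "hyrax", "sheep"),
    c("2019-11-02T06:15", "2019-11-02T06:15", "2019-11-02T06:15")))
  m <- incidence_matrix(ev, stations = c("A", "B", "C"),
                        blocklist = c("Sheep"))
  expect_equal(dim(m), c(1L, 3L))
  expect_equal(unname(m["hyrax", ]), c(1L, 1L, 0L))
})
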