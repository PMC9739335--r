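test_that("overlap-based RI is the complement of D and strictly decreasing", {
  expect_equal(ri_from_overlap(0.45), 0.55)
  expect_equal(ri_from_overlap(1), 0)
  expect_equal(ri_from_overlap(0), 1)
  d <- seq(0, 1, by = 0.05)
  expect_true(all(diff(ri_from_overlap(d)) < 0))
  expect_error(ri_from_overlap(1.2), "\\[0, 1\\]")
  expect_error(ri_from_overlap(-0.1), "\\[0, 1\\]")
})

test_that("asymmetric RI hits its endpoints and flags unobservable barriers", {
  expect_equal(ri_asymmetric(0.4, 0.4), 0)
  expect_equal(ri_asymmetric(0.7, 0), 1)
  expect_equal(ri_asymmetric(0, 0.3), -1)
  expect_warning(out <- ri_asymmetric(0, 0), "unobservable")
  expect_true(is.na(out))
  expect_error(ri_asymmetric(-0.1, 0.5), "non-negative")
})

test_that("asymmetric RI is antisymmetric under swapping roles", {
  set.seed(53)
  for (i in 1:100) {
    w <- runif(1, 0.01, 1); b <- runif(1, 0.01, 1)
    expect_equal(ri_asymmetric(w, b) + ri_asymmetric(b, w), 0)
  }
})

make_cross_row <- function(acceptor, donor, n_poll, n_fruit,
                           seeds = 0L, viable = 0L,
                           pollen = NA_integer_, germ = NA_integer_) {
  data.frame(acceptor = acceptor, donor = donor,
             treatment = if (acceptor == donor) "within" else "between",
             n_pollinations = n_poll, n_fruits = n_fruit,
             n_seeds_total = seeds, n_seeds_viable = viable,
             n_pollen_total = pollen, n_pollen_germinated = germ,
             stringsAsFactors = FALSE)
}

test_that("cross summaries pool counts, not per-record ratios", {
  tab <- rbind(make_cross_row("A", "A", 10L, 5L),
               make_cross_row("A", "B", 10L, 3L),
               make_cross_row("A", "B", 10L, 1L))
  cs <- cross_summaries(tab, "A", "B")
  expect_equal(cs$Pw_fruit, 0.5)   # 5/10
  expect_equal(cs$Pb_fruit, 0.2)   # pooled 4/20, not mean(0.3, 0.1)
})

test_that("pairs below the minimum sample size are flagged missing", {
  tab <- rbind(make_cross_row("A", "A", 10L, 5L),
               make_cross_row("A", "B", 4L, 2L))
  cs <- cross_summaries(tab, "A", "B")
  expect_true(is.na(cs$Pb_fruit))
  expect_true(is.na(cs$Gb))
  expect_equal(cs$n_between, 4)
  # and an acceptor without within-treatment data yields all-missing
  tab2 <- make_cross_row("A", "B", 10L, 3L)
  cs2 <- cross_summaries(tab2, "A", "B")
  expect_true(all(is.na(unlist(cs2[c("Gw", "Gb", "Pw_fruit", "Pb_fruit",
                                     "Pw_seed", "Pb_seed")]))))
})

test_that("pooled mode spans eligible donors; donor-resolved mode does not", {
  tab <- rbind(make_cross_row("A", "A", 10L, 8L),
               make_cross_row("A", "B", 10L, 2L),
               make_cross_row("A", "C", 10L, 6L),
               make_cross_row("A", "D", 3L, 3L)) # below min_n: excluded
  pooled <- cross_summaries(tab, "A", "B")
  expect_equal(pooled$Pb_fruit, 8 / 20) # B and C pooled, D excluded
  solo <- cross_summaries(tab, "A", "B", pooled = FALSE)
  expect_equal(solo$Pb_fruit, 0.2)
})

test_that("summaries on concatenated records equal summaries on pooled counts", {
  split_tab <- rbind(make_cross_row("A", "A", 6L, 3L, 60L, 30L, 100L, 50L),
                     make_cross_row("A", "A", 4L, 3L, 40L, 30L, 100L, 70L),
                     make_cross_row("A", "B", 5L, 2L, 50L, 20L, 120L, 30L),
                     make_cross_row("A", "B", 5L, 3L, 30L, 25L, 80L, 50L))
  merged_tab <- rbind(make_cross_row("A", "A", 10L, 6L, 100L, 60L, 200L, 120L),
                      make_cross_row("A", "B", 10L, 5L, 80L, 45L, 200L, 80L))
  expect_equal(cross_summaries(split_tab, "A", "B"),
               cross_summaries(merged_tab, "A", "B"))
})

test_that("the assembled barrier table covers every directed pair in order", {
  species <- paste0("s", 1:8)
  d_eco <- matrix(runif(64, 0, 1), 8, 8, dimnames = list(species, species))
  d_eco <- (d_eco + t(d_eco)) / 2; diag(d_eco) <- 1
  d_phen <- d_eco * 0.5; diag(d_phen) <- 1
  tab <- assemble_barriers(d_eco, d_phen, crosses = NULL, species = species)
  expect_equal(nrow(tab), 56 * 5) # 8 x 7 directed pairs x 5 barriers
  expect_equal(unique(paste(tab$barrier[1:5])),
               c("ecogeography", "phenology", "pollen_stigma", "fruit_set",
                 "seed_viability"))
  # without crosses the asymmetric barriers are all missing
  expect_true(all(tab$missing[tab$barrier %in%
                                c("pollen_stigma", "fruit_set",
                                  "seed_viability")]))
  # RI_eco is direction-independent (D is symmetric)
  eco <- tab[tab$barrier == "ecogeography", ]
  key <- paste(pmin(eco$acceptor, eco$donor), pmax(eco$acceptor, eco$donor))
  expect_true(all(tapply(eco$ri, key, function(v) diff(range(v)) == 0)))
})

test_that("acceptors lacking cross data keep exactly the two overlap barriers", {
  species <- c("A", "B", "C")
  d <- matrix(0.5, 3, 3, dimnames = list(species, species)); diag(d) <- 1
  crosses <- rbind(make_cross_row("A", "A", 10L, 5L, 50L, 40L, 100L, 60L),
                   make_cross_row("A", "B", 10L, 5L, 50L, 40L, 100L, 55L),
                   make_cross_row("A", "C", 10L, 4L, 40L, 30L, 90L, 50L))
  tab <- assemble_barriers(d, d, crosses, species)
  with_a <- tab[tab$acceptor == "A" & tab$donor == "B", ]
  expect_equal(sum(!with_a$missing), 5)
  no_cross <- tab[tab$acceptor == "B" & tab$donor == "C", ]
  expect_equal(sum(!no_cross$missing), 2)
  expect_equal(no_cross$barrier[!no_cross$missing],
               c("ecogeography", "phenology"))
  expect_error(assemble_barriers(d, d, make_cross_row("A", "Z", 10L, 5L),
                                 species),
               "absent from")
})
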