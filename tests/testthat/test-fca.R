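test_that("Huff probabilities follow capacity and decay weighting", {
  f <- decay_function()

  # single-member catchment
  inst <- tiny_instance(times = c(10, 120), populations = 1000,
                        udas = c(5000, 5000))
  B <- build_catchments(inst$travel, 10)
  P <- huff_probabilities(inst$providers, inst$travel, B, f)
  expect_equal(unname(P[1, ]), c(1, 0))

  # equal capacity, equal times -> symmetric split
  inst <- tiny_instance(times = c(12, 12), populations = 1000,
                        udas = c(4000, 4000))
  B <- build_catchments(inst$travel, 10)
  P <- huff_probabilities(inst$providers, inst$travel, B, f)
  expect_equal(unname(P[1, ]), c(0.5, 0.5))

  # equal times: decay cancels, probabilities proportional to capacity
  inst <- tiny_instance(times = c(10, 10), populations = 1000,
                        udas = c(2000, 1000))
  B <- build_catchments(inst$travel, 10)
  P <- huff_probabilities(inst$providers, inst$travel, B, f)
  expect_equal(unname(P[1, ]), c(2 / 3, 1 / 3))
})

test_that("Huff rows sum to one except for empty catchments", {
  inst <- random_instance(60, 25, seed = 4, p_unreachable = 0.35,
                          p_zero_capacity = 0.1)
  B <- build_catchments(inst$travel, 5)
  P <- huff_probabilities(inst$providers, inst$travel, B,
                          decay_function())
  rs <- rowSums(P)
  expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
  expect_true(all(P >= 0))
  # non-members always get zero weight
  expect_true(all(P[!B$membership] == 0))
})

test_that("demand allocation conserves population of served zones", {
  inst <- tiny_instance(times = c(10, 20, 10, 20),
                        populations = c(1000, 2000),
                        udas = c(3000, 3000))
  B <- build_catchments(inst$travel, 10)
  P <- matrix(0.5, 2, 2, dimnames = dimnames(inst$travel$minutes))
  D <- allocate_demand(P, inst$zones)
  expect_equal(unname(D), c(1500, 1500))
  expect_error(allocate_demand(P[1, , drop = FALSE], inst$zones),
               "dimension")
})

test_that("supply ratios flag zero-demand providers instead of dividing", {
  prov <- data.frame(provider_id = c("a", "b", "c"),
                     uda = c(1500, 10740, 0))
  R <- supply_ratios(prov, c(1000, 0, 500))
  expect_equal(as.numeric(R), c(1.5, 0, 0))
  expect_equal(attr(R, "zero_demand"), c(FALSE, TRUE, FALSE))
  expect_error(supply_ratios(prov, c(-1, 0, 0)), "non-negative")
})

test_that("single zone-provider pair gives SDI = 1000 S / Pop and SPAI = SDI/1000 at zero delta", {
  inst <- tiny_instance(times = 10, populations = 1000, udas = 1500)
  fit <- mhv3sfca(inst$zones, inst$providers, inst$travel)
  expect_equal(fit$zones$sdi, 1500)
  # sole provider: delta = d - d_min = 0, so f = 1 and SPAI = SDI/1000
  expect_equal(fit$zones$spai, 1.5)
  expect_equal(fit$providers$allocated_demand, 1000)
  expect_equal(fit$providers$supply_ratio, 1.5)
})

test_that("raw delta mode applies the decay at the actual travel time", {
  inst <- tiny_instance(times = 30, populations = 1000, udas = 1500)
  fit <- mhv3sfca(inst$zones, inst$providers, inst$travel,
                  delta_mode = "raw")
  expect_equal(fit$zones$sdi, 1500)   # SDI has no decay weight
  expect_equal(fit$zones$spai, 0.05 * 1.5)  # f(30) = 0.05
})

test_that("conservation identities hold on random instances", {
  for (seed in c(2, 9, 23)) {
    inst <- random_instance(50, 20, seed = seed, p_unreachable = 0.2)
    fit <- mhv3sfca(inst$zones, inst$providers, inst$travel)
    z <- fit$zones; p <- fit$providers
    served <- !z$empty_catchment
    expect_equal(sum(p$allocated_demand), sum(z$population[served]),
                 tolerance = 1e-9)
    expect_equal(sum(z$population[served] * z$sdi[served]),
                 1000 * sum(p$uda[!p$zero_demand]),
                 tolerance = 1e-9)
    expect_true(all(z$spai[served] <= z$sdi[served] / 1000 + 1e-12))
  }
})

test_that("indices scale correctly with population and capacity", {
  inst <- random_instance(40, 15, seed = 31)
  base <- mhv3sfca(inst$zones, inst$providers, inst$travel)

  z2 <- inst$zones; z2$population <- 3 * z2$population
  popx <- mhv3sfca(z2, inst$providers, inst$travel)
  expect_equal(popx$zones$sdi, base$zones$sdi / 3, tolerance = 1e-12)
  expect_equal(popx$zones$spai, base$zones$spai / 3, tolerance = 1e-12)
  expect_equal(popx$weights, base$weights, tolerance = 1e-12)

  p2 <- inst$providers; p2$uda <- 2 * p2$uda
  capx <- mhv3sfca(inst$zones, p2, inst$travel)
  expect_equal(capx$zones$sdi, 2 * base$zones$sdi, tolerance = 1e-12)
})

test_that("provider order does not affect results", {
  inst <- random_instance(30, 12, seed = 17)
  base <- mhv3sfca(inst$zones, inst$providers, inst$travel)
  perm <- sample(nrow(inst$providers))
  prov2 <- inst$providers[perm, ]
  fit2 <- mhv3sfca(inst$zones, prov2, inst$travel)
  expect_equal(fit2$zones$sdi, base$zones$sdi)
  expect_equal(fit2$zones$spai, base$zones$spai)
  expect_equal(fit2$providers$allocated_demand[order(perm)],
               base$providers$allocated_demand)
})

test_that("matrix implementation agrees with the per-zone loop reference", {
  inst <- random_instance(50, 30, seed = 11, p_unreachable = 0.25)
  fit <- mhv3sfca(inst$zones, inst$providers, inst$travel)
  ref <- mhv3sfca_naive(inst$zones, inst$providers, inst$travel)
  expect_equal(fit$zones$sdi, ref$zones$sdi, tolerance = 1e-10)
  expect_equal(fit$zones$spai, ref$zones$spai, tolerance = 1e-10)
  expect_equal(fit$providers$allocated_demand,
               ref$providers$allocated_demand, tolerance = 1e-10)
  expect_equal(fit$zones$empty_catchment, ref$zones$empty_catchment)

  # raw mode too
  fit_r <- mhv3sfca(inst$zones, inst$providers, inst$travel,
                    delta_mode = "raw")
  ref_r <- mhv3sfca_naive(inst$zones, inst$providers, inst$travel,
                          delta_mode = "raw")
  expect_equal(fit_r$zones$spai, ref_r$zones$spai, tolerance = 1e-10)
})

test_that("zones with no reachable provider get missing indices", {
  m <- matrix(c(10, 20,
                120, 120), nrow = 2, byrow = TRUE,
              dimnames = list(c("z1", "z2"), c("p1", "p2")))
  zones <- data.frame(zone_id = c("z1", "z2"), population = c(1000, 1000))
  providers <- data.frame(provider_id = c("p1", "p2"), uda = c(5000, 5000))
  fit <- mhv3sfca(zones, providers, travel_matrix(m))
  expect_false(fit$zones$empty_catchment[1])
  expect_true(fit$zones$empty_catchment[2])
  expect_true(is.na(fit$zones$sdi[2]) && is.na(fit$zones$spai[2]))
  ref <- mhv3sfca_naive(zones, providers, travel_matrix(m))
  expect_true(is.na(ref$zones$sdi[2]))
  # demand conservation counts only the served zone
  expect_equal(sum(fit$providers$allocated_demand), 1000)
})

test_that("q_target = 1 reduces to nearest-provider allocation", {
  inst <- random_instance(25, 10, seed = 13, p_unreachable = 0)
  fit <- mhv3sfca(inst$zones, inst$providers, inst$travel, q_target = 1)
  # without ties every row has exactly one member with probability 1
  single <- fit$catchment$effective_q == 1
  expect_true(all(apply(fit$weights[single, , drop = FALSE], 1,
                        function(r) sum(r > 0) == 1 && max(r) == 1)))
  ref <- mhv3sfca_naive(inst$zones, inst$providers, inst$travel,
                        q_target = 1)
  expect_equal(fit$zones$sdi, ref$zones$sdi, tolerance = 1e-10)
})

test_that("input validation reports offending records", {
  inst <- random_instance(5, 3, seed = 1)
  z <- inst$zones; z$population[2] <- 0
  expect_error(mhv3sfca(z, inst$providers, inst$travel),
               "non-positive population.*z002")
  z <- inst$zones; z$zone_id[2] <- z$zone_id[1]
  expect_error(mhv3sfca(z, inst$providers, inst$travel), "duplicated")
  p <- inst$providers; p$uda[1] <- -5
  expect_error(mhv3sfca(inst$zones, p, inst$travel), "negative capacity")
})
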