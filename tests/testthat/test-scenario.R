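test_that("edits reshape the inputs as described", {
  inst <- random_instance(10, 3, seed = 6, p_unreachable = 0)

  cut <- apply_edits(inst$zones, inst$providers, inst$travel,
                     edit_remove_provider("p002"))
  expect_equal(ncol(cut$travel$minutes), 2L)
  expect_equal(cut$providers$provider_id, c("p001", "p003"))

  # adding a provider at an existing provider's coordinates duplicates its
  # travel column (travel must derive from coordinates for this to hold)
  ci <- coord_instance(15, 4, seed = 6)
  j <- ci$providers[2, ]
  add <- apply_edits(ci$zones, ci$providers, ci$travel,
                     edit_add_provider("pNEW", 9000, j$x_km, j$y_km))
  expect_equal(unname(add$travel$minutes[, "pNEW"]),
               unname(ci$travel$minutes[, j$provider_id]))

  # sequential semantics: set_capacity then remove -> removal wins
  seqed <- apply_edits(inst$zones, inst$providers, inst$travel,
                       list(edit_set_capacity("p001", 99999),
                            edit_remove_provider("p001")))
  expect_false("p001" %in% seqed$providers$provider_id)

  zedit <- apply_edits(inst$zones, inst$providers, inst$travel,
                       list(edit_remove_zone("z003"),
                            edit_set_population("z001", 4321)))
  expect_equal(nrow(zedit$travel$minutes), 9L)
  expect_equal(zedit$zones$population[zedit$zones$zone_id == "z001"], 4321)

  expect_error(apply_edits(inst$zones, inst$providers, inst$travel,
                           edit_remove_provider("nope")), "unknown provider")
  expect_error(apply_edits(inst$zones, inst$providers, inst$travel,
                           edit_add_provider("p001", 1, 0, 0)),
               "already exists")
  expect_error(edit_set_capacity("p001", -10), "uda")
  expect_error(edit_set_population("z001", 0), "persons")
})

test_that("an empty edit list leaves indices and ranks unchanged", {
  inst <- random_instance(30, 8, seed = 8)
  sc <- run_scenario(inst$zones, inst$providers, inst$travel, list())
  d <- sc$delta
  expect_equal(d$sdi_with, d$sdi_without)
  expect_equal(d$spai_with, d$spai_without)
  expect_true(all(d$sdi_rank_change[!is.na(d$sdi_rank_change)] == 0))
  expect_equal(sc$n_catchment_changed, 0L)
})

test_that("remove-then-restore round-trips to the baseline", {
  inst <- coord_instance(40, 10, seed = 19)
  j <- inst$providers[5, ]
  sc <- run_scenario(inst$zones, inst$providers, inst$travel,
                     list(edit_remove_provider(j$provider_id),
                          edit_add_provider(j$provider_id, j$uda,
                                            j$x_km, j$y_km)))
  expect_equal(sc$delta$sdi_without, sc$delta$sdi_with, tolerance = 1e-9)
  expect_equal(sc$delta$spai_without, sc$delta$spai_with, tolerance = 1e-9)
})

test_that("removing the dominant provider shifts the mean SDI by its capacity share", {
  # dense region: every provider keeps positive demand before and after
  inst <- random_instance(60, 12, seed = 3, p_unreachable = 0)
  fit0 <- mhv3sfca(inst$zones, inst$providers, inst$travel)
  expect_true(all(!fit0$providers$zero_demand))
  big <- inst$providers$provider_id[which.max(inst$providers$uda)]
  sc <- run_scenario(inst$zones, inst$providers, inst$travel,
                     list(edit_remove_provider(big)))
  expect_true(all(!sc$scenario$providers$zero_demand))
  d <- sc$delta
  pw_before <- weighted.mean(d$sdi_with, d$population)
  pw_after <- weighted.mean(d$sdi_without, d$population)
  drop_expected <- 1000 * max(inst$providers$uda) / sum(d$population)
  expect_equal(pw_before - pw_after, drop_expected, tolerance = 1e-9)
  # a closure cannot raise availability anywhere
  expect_true(all(d$sdi_without <= d$sdi_with + 1e-9))
})

test_that("zones with unchanged catchments keep their Huff rows", {
  inst <- random_instance(50, 15, seed = 21, p_unreachable = 0.2)
  big <- inst$providers$provider_id[which.max(inst$providers$uda)]
  sc <- run_scenario(inst$zones, inst$providers, inst$travel,
                     list(edit_remove_provider(big)))
  mb <- sc$baseline$catchment$membership
  keep <- !mb[, big]  # zones that never had the removed provider
  if (any(keep)) {
    pb <- sc$baseline$weights[keep, colnames(mb) != big, drop = FALSE]
    pa <- sc$scenario$weights[keep, , drop = FALSE]
    expect_equal(unname(pb), unname(pa), tolerance = 1e-12)
  }
})

test_that("ranking is dense over defined values with average ties", {
  z <- data.frame(zone_id = c("a", "b", "c"),
                  sdi = c(3, 1, 2), spai = c(2, 2, 1),
                  stringsAsFactors = FALSE)
  expect_equal(unname(rank_table(z, "sdi")), c(1, 3, 2))
  expect_equal(unname(rank_table(z, "spai")), c(1.5, 1.5, 3))
  z$sdi <- NA_real_
  expect_true(all(is.na(rank_table(z, "sdi"))))
})

test_that("scenario files in YAML and JSON parse to the same edits", {
  skip_if_not_installed("yaml")
  skip_if_not_installed("jsonlite")
  recs <- list(list(op = "remove_provider", id = "p001"),
               list(op = "set_capacity", id = "p002", uda = 5000))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(recs, yml)
  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE), jsn)
  e1 <- read_scenario(yml)
  e2 <- read_scenario(jsn)
  expect_equal(e1, e2)
  expect_s3_class(e1[[1]], "fca_edit")
  expect_equal(e1[[2]]$uda, 5000)
})
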