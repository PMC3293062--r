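# Image generator -------------------------------------------------------------

test_that("image generation is a pure function of (params, size, seed)", {
  p <- texture_class_params(delta = 0.5)
  a <- make_texture_image(p, c(96, 96), seed = 11)
  b <- make_texture_image(p, c(96, 96), seed = 11)
  expect_identical(a$pixels, b$pixels)
  c <- make_texture_image(p, c(96, 96), seed = 12)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("zero density and zero noise give a constant background field", {
  p <- texture_class_params(density = 0, noise_sd = 0, delta = 0.3)
  img <- make_texture_image(p, c(64, 64), seed = 1)
  expect_equal(length(unique(as.vector(img$pixels))), 1)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(texture_class_params(delta = 1.5), "delta")
  expect_error(texture_class_params(p_fill = -0.1), "p_fill")
  expect_error(texture_class_params(radius_range = c(5, 2)))
  expect_error(make_texture_image(texture_class_params(), c(32, 32)),
               "64 x 64")
})

test_that("impossible packing densities fail with actionable advice", {
  p <- texture_class_params(density = 40, radius_range = c(30, 32))
  expect_error(make_texture_image(p, c(96, 96), seed = 1), "density")
})

test_that("degenerate and intact classes are separated by texture features", {
  imgs <- list(); groups <- character(0)
  for (i in 1:8) {
    imgs[[length(imgs) + 1L]] <-
      make_texture_image(texture_class_params(delta = 0), c(160, 160),
                         seed = 100 + i)
    groups <- c(groups, "intact")
  }
  for (i in 1:8) {
    imgs[[length(imgs) + 1L]] <-
      make_texture_image(texture_class_params(delta = 1), c(160, 160),
                         seed = 200 + i)
    groups <- c(groups, "degenerated")
  }
  tab <- extract_features(imgs,
                          data.frame(sample_id = sprintf("i%02d", 1:16),
                                     group = groups),
                          distances = 1:2)
  ent <- split(tab$com_d1_entropy, tab$group)
  pooled_sd <- sqrt(mean(c(var(ent$intact), var(ent$degenerated))))
  effect <- abs(mean(ent$intact) - mean(ent$degenerated)) / pooled_sd
  expect_gt(effect, 5)
})

test_that("mean co-occurrence entropy falls monotonically with degeneration", {
  deltas <- c(0, 0.35, 0.7, 1)
  mean_ent <- vapply(seq_along(deltas), function(i) {
    imgs <- lapply(1:4, function(j) {
      make_texture_image(texture_class_params(delta = deltas[i]),
                         c(160, 160), seed = 1000 * i + j)
    })
    tab <- extract_features(imgs, distances = 1)
    mean(tab$com_d1_entropy)
  }, numeric(1))
  expect_true(all(diff(mean_ent) < 0))
})

test_that("datasets carry one labeled row of metadata per image", {
  ds <- make_image_dataset(n_images = 2, size = c(64, 64), seed = 3)
  expect_length(ds$images, 10)                 # 5 default groups x 2
  expect_equal(nrow(ds$metadata), 10)
  expect_setequal(unique(ds$metadata$group),
                  c("N", "CIS", "CIS+L", "CIS+M", "CIS+H"))
  expect_false(anyDuplicated(ds$metadata$sample_id) > 0)
  single <- make_image_dataset(list(g = texture_class_params()),
                               n_images = 1, size = c(64, 64), seed = 4)
  expect_length(single$images, 1)
  dup <- list(a = texture_class_params(), a = texture_class_params())
  expect_error(make_image_dataset(dup, n_images = 1, size = c(64, 64)),
               "uniquely named")
})

# Animal-table generator ------------------------------------------------------

test_that("the shipped group specs cover six groups and eight indicators", {
  specs <- group_indicator_specs()
  expect_setequal(names(specs), c("N", "GB", "CIS", "CIS+L", "CIS+M", "CIS+H"))
  for (g in names(specs)) {
    expect_setequal(names(specs[[g]]),
                    c("Testis_W", "Epidid_W", "SpC", "SpM", "MDA", "MPO",
                      "CAT", "SOD"))
  }
  expect_equal(attr(specs, "n_animals"), 10L)
})

test_that("animal tables are deterministic given the seed", {
  a <- make_animal_table(seed = 21)
  b <- make_animal_table(seed = 21)
  expect_identical(a, b)
  expect_equal(nrow(a), 60)                     # 6 groups x 10 animals
  expect_false(identical(a, make_animal_table(seed = 22)))
})

test_that("a zero error term collapses every animal onto the group mean", {
  spec <- list(G = lapply(
    c(Testis_W = 3.5, Epidid_W = 1.6, SpC = 130, SpM = 79, MDA = 1,
      MPO = 17, CAT = 147, SOD = 3.4),
    function(m) list(mean = m, se = 0)))
  tab <- make_animal_table(spec, n_animals = 5, seed = 1)
  expect_true(all(tab$CAT == 147))
  expect_true(all(tab$SpM == 79))
})

test_that("negative draws of positive quantities are truncated with warning", {
  spec <- list(G = lapply(
    c(Testis_W = 0.01, Epidid_W = 1, SpC = 100, SpM = 50, MDA = 1,
      MPO = 17, CAT = 147, SOD = 3.4),
    function(m) list(mean = m, se = 5)))
  expect_warning(tab <- make_animal_table(spec, n_animals = 20, seed = 2),
                 "truncated")
  expect_true(all(tab$Testis_W >= 0))
})

test_that("large simulations recover the published group means", {
  specs <- group_indicator_specs()
  tab <- make_animal_table(specs["N"], n_animals = 10000, seed = 3)
  expect_equal(mean(tab$CAT), 146.79, tolerance = 0.005)   # within 0.5%
  expect_equal(mean(tab$MDA), 0.97, tolerance = 0.005)
})

test_that("group means are recovered within 3 SE at the study group size", {
  specs <- group_indicator_specs()
  inds <- c("Testis_W", "Epidid_W", "SpC", "SpM", "MDA", "MPO", "CAT", "SOD")
  hits <- 0; total <- 0
  for (seed in 1:20) {
    tab <- make_animal_table(specs["N"], n_animals = 10, seed = 300 + seed)
    for (ind in inds) {
      total <- total + 1
      m <- specs$N[[ind]]$mean; se <- specs$N[[ind]]$se
      # sample mean of n draws with SD = se*sqrt(n) has SE = se
      if (abs(mean(tab[[ind]]) - m) <= 3 * se) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("treating the error terms as SDs narrows the simulated spread", {
  specs <- group_indicator_specs()
  wide <- make_animal_table(specs["N"], n_animals = 200, seed = 4,
                            spread = "se")
  narrow <- make_animal_table(specs["N"], n_animals = 200, seed = 4,
                              spread = "sd")
  expect_gt(sd(wide$CAT), 2 * sd(narrow$CAT))
})

test_that("a missing indicator in a custom spec is an error", {
  spec <- list(G = list(Testis_W = list(mean = 1, se = 0.1)))
  expect_error(make_animal_table(spec), "missing indicator")
})
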