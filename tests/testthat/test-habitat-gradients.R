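grad_fixture <- function() {
  gradient("wet_dry",
           c("extensive_wetland", "linear_fragmented_wetland", "damp", "dry"),
           list(reedbed = "extensive_wetland",
                rice_field = "linear_fragmented_wetland",
                ditch = "linear_fragmented_wetland",
                wet_grassland = "damp",
                arable = "dry",
                span = c("damp", "dry")))
}

test_that("position score takes the maximum over mapped habitats", {
  g <- grad_fixture()
  sc <- matrix(c(2, 1, 0, 0, 1, 0), nrow = 1,
               dimnames = list("sp1", c("rice_field", "ditch", "reedbed",
                                        "wet_grassland", "arable", "span")))
  expect_equal(position_score("sp1", "linear_fragmented_wetland", sc, g), 2)
  expect_equal(position_score("sp1", "extensive_wetland", sc, g), 0)
  expect_equal(position_score("sp1", "dry", sc, g), 1)      # max(arable, span)
  expect_error(position_score("sp1", "nowhere", sc, g), "unknown")
})

test_that("positions with no mapped habitat score zero; zero-score habitats are inert", {
  g <- gradient("g", c("a", "b"), list(h1 = "a"))
  sc <- matrix(1, 1, 1, dimnames = list("sp", "h1"))
  expect_equal(position_score("sp", "b", sc, g), 0)
  expect_equal(position_score("sp", "a", sc, g), 1)
  # adding a habitat scored 0 at the same position changes nothing
  g2 <- gradient("g", c("a", "b"), list(h1 = "a", h2 = "a"))
  sc2 <- cbind(sc, h2 = 0)
  expect_equal(position_score("sp", "a", sc2, g2), 1)
})

test_that("a habitat spanning categories counts at each", {
  g <- grad_fixture()
  sc <- matrix(2, 1, 1, dimnames = list("sp", "span"))
  expect_equal(position_score("sp", "damp", sc, g), 2)
  expect_equal(position_score("sp", "dry", sc, g), 2)
})

test_that("group profiles give means, SEs and degenerate flags", {
  g <- grad_fixture()
  species <- data.frame(species_id = c("n1", "n2", "x1"),
                        status = c("native", "native", "nonnative"))
  sc <- matrix(c(2, 0, 0, 0, 0, 0,
                 2, 0, 0, 0, 0, 0,
                 0, 2, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("n1", "n2", "x1"),
                               c("arable", "rice_field", "reedbed",
                                 "wet_grassland", "ditch", "span")))
  prof <- group_profile(sc, g, species)
  nat_dry <- prof[prof$group == "native" & prof$position == "dry", ]
  expect_equal(nat_dry$mean, 2)
  expect_equal(nat_dry$se, 0)        # identical scores -> SE 0
  non <- prof[prof$group == "nonnative", ]
  expect_true(all(is.na(non$se)))    # single species -> SE undefined
  expect_error(group_profile(sc[1:2, ], g,
                             species[species$status == "native", ]), "nonnative")
})

test_that("max divergence finds the programmed peak and reports ties", {
  g <- grad_fixture()
  species <- data.frame(species_id = c("n1", "n2", "x1", "x2"),
                        status = c("native", "native", "nonnative", "nonnative"))
  sc <- matrix(0, 4, 2, dimnames = list(species$species_id,
                                        c("rice_field", "arable")))
  sc[c("x1", "x2"), "rice_field"] <- 2
  sc[c("n1", "n2"), "arable"] <- 1
  prof <- group_profile(sc, g, species)
  mx <- max_divergence_position(prof)
  expect_equal(mx$position, "linear_fragmented_wetland")
  expect_equal(mx$difference, 2)

  # identical profiles: every position tied at zero difference
  sc0 <- matrix(1, 4, 1, dimnames = list(species$species_id, "rice_field"))
  mx0 <- max_divergence_position(group_profile(sc0, g, species))
  expect_equal(nrow(mx0), length(g$categories))
  expect_true(all(mx0$difference == 0))
})

test_that("gradient YAML round trip and validation", {
  g <- grad_fixture()
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = g$name, categories = g$categories,
                        habitat_map = g$habitat_map), path)
  g2 <- read_gradient(path)
  expect_equal(g2$categories, g$categories)
  expect_equal(g2$habitat_map[["span"]], c("damp", "dry"))
  expect_error(gradient("bad", c("a", "b"), list(h = "zzz")), "unknown")
})

test_that("default gradients have the canonical category counts", {
  gs <- default_gradients()
  expect_length(gs$wet_dry$categories, 4)
  expect_length(gs$open_closed$categories, 6)
  # rice fields sit mid-gradient on both
  expect_true("rice_field" %in% names(gs$wet_dry$habitat_map))
  expect_true("rice_field" %in% names(gs$open_closed$habitat_map))
})

test_that("generated scores diverge maximally at the rice-field positions", {
  species <- data.frame(species_id = c(sprintf("NAT%02d", 1:8),
                                       sprintf("NON%02d", 1:4)),
                        status = rep(c("native", "nonnative"), c(8, 4)))
  sc <- generate_gradient_scores(species, seed = 5)
  gs <- default_gradients()
  prof <- group_profile(sc, gs$wet_dry, species)
  mx <- max_divergence_position(prof)
  rice_pos <- gs$wet_dry$habitat_map[["rice_field"]]
  expect_true(rice_pos %in% mx$position)
})
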