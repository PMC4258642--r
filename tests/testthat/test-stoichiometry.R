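test_that("species parsing reads formulas and both charge dialects", {
  cases <- list(
    list("SO4^2-", c(S = 1L, O = 4L), -2L),
    list("SO42-",  c(S = 1L, O = 4L), -2L),
    list("CH2O",   c(C = 1L, H = 2L, O = 1L), 0L),
    list("FeOOH",  c(Fe = 1L, O = 2L, H = 1L), 0L),
    list("Fe^2+",  c(Fe = 1L), 2L),
    list("Fe2+",   c(Fe = 1L), 2L),
    list("H+",     c(H = 1L), 1L),
    list("H2O",    c(H = 2L, O = 1L), 0L))
  for (cs in cases) {
    sp <- parse_species(cs[[1]])
    expect_equal(sp$composition[order(names(sp$composition))],
                 cs[[2]][order(names(cs[[2]]))], info = cs[[1]])
    expect_identical(sp$charge, cs[[3]], info = cs[[1]])
  }
  # same species in either dialect gets the same canonical label
  expect_identical(parse_species("Fe^2+")$label, parse_species("Fe2+")$label)
  expect_error(parse_species("Xx2O"), "unknown element")
  expect_error(parse_species("Fe^2*"), "charge|parse")
})

test_that("all six packaged reactions balance exactly in atoms and charge", {
  eqs <- redox_reactions()
  expect_setequal(names(eqs), c("photoferrotrophy", "feIII_respiration", "sulfate_respiration",
                             "methanogenesis", "photoferrotrophy + sulfate_respiration",
                             "photoferrotrophy + methanogenesis"))
  for (id in names(eqs)) {
    rep <- balance_report(eqs[[id]])
    expect_true(rep$balanced, info = id)
    for (e in names(rep$element_net))
      expect_identical(rep$element_net[[e]]$num, 0, info = paste(id, e))
    expect_identical(rep$charge_net$num, 0, info = id)
  }
})

test_that("an off-by-one proton coefficient is caught with exact nets", {
  broken <- parse_reaction(
    "2 CO2 + 8 Fe^2+ + 14 H2O -> 2 CH2O + 8 FeOOH + 15 H+")
  rep <- balance_report(broken)
  expect_false(rep$balanced)
  expect_identical(rep$element_net$H$num, -1)
  expect_identical(rep$charge_net$num, -1)
})

test_that("combining primary production with degradation reproduces the printed net rows", {
  eqs <- redox_reactions()
  same_terms <- function(a, b) {
    expect_setequal(names(a$coef), names(b$coef))
    for (l in names(a$coef)) {
      expect_identical(a$coef[[l]]$num, b$coef[[l]]$num, info = l)
      expect_identical(a$coef[[l]]$den, b$coef[[l]]$den, info = l)
    }
  }
  same_terms(combine_reactions(eqs$photoferrotrophy, eqs$sulfate_respiration), eqs$`photoferrotrophy + sulfate_respiration`)
  same_terms(combine_reactions(eqs$photoferrotrophy, eqs$methanogenesis), eqs$`photoferrotrophy + methanogenesis`)
  # the combined rows carry 14 and 16 product protons respectively
  expect_identical(eqs$`photoferrotrophy + sulfate_respiration`$coef[["H^+"]]$num, 14)
  expect_identical(eqs$`photoferrotrophy + methanogenesis`$coef[["H^+"]]$num, 16)
  expect_error(combine_reactions(eqs$photoferrotrophy, eqs$photoferrotrophy, 1, -1), "cancellation")
})

test_that("linear combinations of balanced reactions stay balanced", {
  eqs <- redox_reactions()
  set.seed(42)
  for (i in 1:25) {
    a <- random_registry_reaction(eqs)
    b <- random_registry_reaction(eqs)
    sa <- rational(sample(1:5, 1), sample(1:4, 1))
    sb <- rational(sample(1:5, 1), sample(1:4, 1))
    comb <- tryCatch(combine_reactions(a, b, sa, sb),
                     error = function(e) NULL)  # full cancellation allowed
    if (!is.null(comb)) {
      expect_true(balance_report(comb)$balanced,
                  info = sprintf("%s + %s (%s, %s)", a$id, b$id,
                                 format(sa), format(sb)))
      # normalization leaves integer coefficients in lowest terms
      nums <- vapply(comb$coef, function(r) r$num, 0)
      dens <- vapply(comb$coef, function(r) r$den, 0)
      expect_true(all(dens == 1))
      g <- Reduce(function(x, y) ironcline:::gcd2(x, y), abs(nums))
      expect_identical(g, 1)
    }
  }
})

test_that("donor-per-carbon ratio reads reactant coefficients and ignores scaling", {
  eqs <- redox_reactions()
  expect_identical(donor_per_carbon_ratio(eqs$photoferrotrophy, "Fe^2+", "CO2"), 4)
  expect_identical(donor_per_carbon_ratio(eqs$sulfate_respiration, "CH2O", "SO4^2-"), 2)
  c14 <- combine_reactions(eqs$photoferrotrophy, eqs$methanogenesis)
  expect_identical(donor_per_carbon_ratio(c14, "Fe^2+", "CO2"), 8)
  # uniform scaling of the reaction leaves the ratio unchanged
  scaled <- reaction("scaled", eqs$photoferrotrophy$species,
                     lapply(eqs$photoferrotrophy$coef,
                            function(r) ironcline:::rat_mul(r, rational(7, 3))))
  expect_identical(donor_per_carbon_ratio(scaled, "Fe^2+", "CO2"), 4)
  expect_error(donor_per_carbon_ratio(eqs$methanogenesis, "Fe^2+", "CO2"), "absent")
})

test_that("reaction parsing round-trips through rendering", {
  eqs <- redox_reactions()
  for (id in names(eqs)) {
    r2 <- parse_reaction(format_reaction(eqs[[id]]), id = id)
    expect_setequal(names(r2$coef), names(eqs[[id]]$coef))
    for (l in names(r2$coef))
      expect_identical(r2$coef[[l]]$num, eqs[[id]]$coef[[l]]$num,
                       info = paste(id, l))
  }
})
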