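make_balance_toy <- function() {
  m <- new_model("bal", c(c = "cytosol", e = "extracellular"))
  mets <- list(
    glc = c("C6H12O6", 0), g6p = c("C6H11O9P", -2),
    atp = c("C10H12N5O13P3", -4), adp = c("C10H12N5O10P2", -3),
    h = c("H", 1), h2o = c("H2O", 0), pi = c("HO4P", -2))
  for (nm in names(mets)) {
    m <- add_metabolite(m, paste0(nm, "_c"), formula = mets[[nm]][1],
                        charge = as.integer(mets[[nm]][2]))
  }
  m
}

test_that("hand-summed element and charge nets match the audit", {
  m <- make_balance_toy()
  # hexokinase, correctly written: balanced exactly
  m <- add_reaction(m, "HEX", c(glc_c = -1, atp_c = -1, g6p_c = 1,
                                adp_c = 1, h_c = 1))
  # ATP hydrolysis with the water omitted: net -H2O on the left
  m <- add_reaction(m, "BADHYD", c(atp_c = -1, adp_c = 1, pi_c = 1, h_c = 1))
  rep <- check_balance(m)
  expect_equal(rep$n_checked, 2)
  expect_false("HEX" %in% names(rep$unbalanced))
  expect_true("BADHYD" %in% names(rep$unbalanced))
  net <- rep$unbalanced$BADHYD$elements
  # independent hand-sum: products minus reactants of the broken reaction
  expect_equal(net[["H"]], 2)
  expect_equal(net[["O"]], 1)
  expect_equal(rep$unbalanced$BADHYD$charge, 0)
})

test_that("boundary reactions are exempt and empty models report nothing", {
  m <- make_balance_toy()
  m <- add_reaction(m, "EX_glc", c(glc_c = -1), kind = "exchange")
  m <- add_reaction(m, "DM_pi", c(pi_c = -1), kind = "demand")
  rep <- check_balance(m)
  expect_equal(rep$n_checked, 0)
  expect_length(rep$unbalanced, 0)
  empty <- new_model("none")
  expect_length(check_balance(empty)$unbalanced, 0)
})

test_that("metabolites without formula make a reaction unauditable, not skipped", {
  m <- make_balance_toy()
  m <- add_metabolite(m, "mys_c", formula = NA_character_, charge = NA_integer_)
  m <- add_reaction(m, "R1", c(glc_c = -1, mys_c = 1))
  rep <- check_balance(m)
  expect_identical(rep$unauditable$R1, "mys_c")
})

test_that("fractional coefficients are audited to tolerance, integers exactly", {
  m <- make_balance_toy()
  m <- add_reaction(m, "HALF", c(h2o_c = -0.5, h_c = 0.5))  # 0.5 OH missing
  expect_true("HALF" %in% names(check_balance(m)$unbalanced))
  # a fractional-coefficient reaction within 1e-6 net passes ...
  m2 <- make_balance_toy()
  m2 <- add_metabolite(m2, "h2oiso_c", formula = "H2O", charge = 0L)
  m2 <- add_reaction(m2, "ISO", c(h2o_c = -(1 + 1e-9), h2oiso_c = 1))
  expect_false("ISO" %in% names(check_balance(m2)$unbalanced))
  # ... but the same slack with integer coefficients is judged exactly
  m3 <- make_balance_toy()
  m3 <- add_metabolite(m3, "hx_c", formula = "H2", charge = 0L)
  m3 <- add_reaction(m3, "INT", c(h2o_c = -1, hx_c = 1))
  expect_true("INT" %in% names(check_balance(m3)$unbalanced))
})

test_that("adding a balanced reaction never changes other reactions' verdicts", {
  m <- make_balance_toy()
  m <- add_reaction(m, "BADHYD", c(atp_c = -1, adp_c = 1, pi_c = 1, h_c = 1))
  before <- check_balance(m)$unbalanced
  m2 <- add_reaction(m, "HEX", c(glc_c = -1, atp_c = -1, g6p_c = 1,
                                 adp_c = 1, h_c = 1))
  after <- check_balance(m2)$unbalanced
  expect_identical(before, after)
})
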