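#' Fatty-acid composition dataset (FAME measurements)
#'
#' Per-condition fatty-acid contents in wt% of cell dry weight.  The
#' total fatty-acid content of a sample, `x`, is defined as the sum of
#' its per-fatty-acid contents, so compositional closure (`sum(y) == x`)
#' holds by construction.
#'
#' @param data either a long data.frame with columns `condition`,
#'   `fatty_acid`, `wt_percent_cdw`, or a numeric matrix (samples x
#'   fatty acids, rownames = conditions).
#' @return a `fame_dataset`: list with `y` (matrix), `x` (row sums),
#'   `conditions`, `fatty_acids`.
#' @export
fame_dataset <- function(data) {
  if (is.data.frame(data)) {
    stopifnot(all(c("condition", "fatty_acid", "wt_percent_cdw") %in% names(data)))
    y <- tapply(data$wt_percent_cdw, list(data$condition, data$fatty_acid), sum)
    y[is.na(y)] <- 0
    y <- as.matrix(y)
  } else {
    y <- as.matrix(data)
  }
  if (any(y < 0)) stop("fatty-acid contents must be nonnegative")
  if (is.null(colnames(y))) colnames(y) <- paste0("FA", seq_len(ncol(y)))
  if (is.null(rownames(y))) rownames(y) <- paste0("S", seq_len(nrow(y)))
  structure(list(y = y, x = rowSums(y), conditions = rownames(y),
                 fatty_acids = colnames(y)), class = "fame_dataset")
}

#' Segmented-regression split of fatty-acid data into lean and lipid-body
#' composition
#'
#' Fits, for each fatty acid k, the line `y_k = m_k (x - x0) + b_k` with a
#' breakpoint `x0` shared across fatty acids, where `x` is a sample's
#' total fatty-acid content (wt% CDW).  The intercepts `b_k` are the
#' fatty-acid contents of "lean" cell mass (mostly membrane
#' phospholipids); the slopes `m_k` are the mass-fraction composition of
#' the accumulating lipid body (triacylglycerols and sterol esters).
#' Closure makes `sum(m) = 1` and `sum(b) = x0` identities.
#'
#' `x0` is found by grid search over `[0, min(x)]`: at each grid point
#' every fatty acid is fit by nonnegative least squares (slopes and
#' intercepts clamped at 0) and the joint residual sum of squares is
#' recorded.  Because all samples lie at `x >= x0`, the RSS is constant in
#' `x0` wherever no nonnegativity constraint binds; the fit therefore
#' takes the largest grid value attaining the minimum (ties at relative
#' 1e-9), i.e. the leanest observed sample when all intercepts remain
#' nonnegative there.  Fatty acids are classified as increasing when
#' their slope exceeds `slope_threshold` and its t-statistic exceeds
#' `t_threshold`; the rest are treated as constant (slope pinned to 0,
#' intercept = mean content) and the closure identities are restored by
#' rescaling.
#'
#' @param data a `fame_dataset` (or something [fame_dataset()] accepts).
#' @param grid_step breakpoint grid resolution, wt% CDW.
#' @param slope_threshold minimal slope for the increasing class
#'   (dimensionless mass fraction).
#' @param t_threshold minimal slope t-statistic for the increasing class.
#' @return a `fame_fit`: list with `m`, `b` (named per fatty acid), `x0`,
#'   `increasing` (logical), `rss`, `lean_composition` (`b/sum(b)`),
#'   `lipid_body_composition` (normalized `m` over the increasing set).
#' @export
fit_segmented <- function(data, grid_step = 0.05, slope_threshold = 0.02,
                          t_threshold = 2) {
  if (!inherits(data, "fame_dataset")) data <- fame_dataset(data)
  y <- data$y; x <- data$x
  if (nrow(y) < 3L) stop("need at least 3 samples to fit")
  if (length(unique(round(x, 10))) < 2L) {
    stop("need at least 2 distinct total fatty-acid contents (x values)")
  }
  K <- ncol(y)
  grid <- seq(0, min(x), by = grid_step)
  if (abs(grid[length(grid)] - min(x)) > 1e-12) grid <- c(grid, min(x))
  # nonnegative least squares of y on (x - x0): intercept + slope, both >= 0
  nnls2 <- function(yk, z) {
    n <- length(z)
    zbar <- mean(z); ybar <- mean(yk)
    szz <- sum((z - zbar)^2)
    slope <- if (szz > 0) sum((z - zbar) * (yk - ybar)) / szz else 0
    inter <- ybar - slope * zbar
    if (inter >= 0 && slope >= 0) {
      rss <- sum((yk - inter - slope * z)^2)
    } else {
      # boundary candidates: intercept pinned at 0, or slope pinned at 0
      s0 <- max(sum(yk * z) / sum(z^2), 0)        # through origin
      r0 <- sum((yk - s0 * z)^2)
      b0 <- max(ybar, 0)                          # constant
      r1 <- sum((yk - b0)^2)
      if (r0 <= r1) { slope <- s0; inter <- 0; rss <- r0 }
      else { slope <- 0; inter <- b0; rss <- r1 }
    }
    se <- if (szz > 0 && n > 2) sqrt(max(sum((yk - inter - slope * z)^2), 0) /
                                       ((n - 2) * szz)) else 0
    c(slope = slope, inter = inter, rss = rss, se = se)
  }
  rss_grid <- numeric(length(grid))
  fits <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    z <- x - grid[gi]
    f <- vapply(seq_len(K), function(k) nnls2(y[, k], z), numeric(4))
    fits[[gi]] <- f
    rss_grid[gi] <- sum(f["rss", ])
  }
  best <- min(rss_grid)
  tied <- which(rss_grid <= best * (1 + 1e-9) + 1e-12)
  gi <- max(tied)                     # largest tied breakpoint
  x0 <- grid[gi]
  f <- fits[[gi]]
  m_hat <- f["slope", ]; b_hat <- f["inter", ]; se <- f["se", ]
  tstat <- ifelse(se > 0, m_hat / se, ifelse(m_hat > 0, Inf, 0))
  increasing <- m_hat > slope_threshold & tstat > t_threshold
  if (!any(increasing)) {
    stop("no lipid-body signal: no fatty acid increases with total content")
  }
  # refit: constant fatty acids pinned to slope 0
  m <- ifelse(increasing, m_hat, 0)
  b <- ifelse(increasing, b_hat, pmax(colMeans(y), 0))
  # closure projection: sum(m) = 1 over the increasing set, sum(b) = x0
  m[increasing] <- m[increasing] / sum(m[increasing])
  if (x0 > 0) {
    if (sum(b) > 0) b <- b * (x0 / sum(b))
  } else {
    b[] <- 0
  }
  z <- x - x0
  rss <- sum((y - matrix(b, nrow(y), K, byrow = TRUE) -
                outer(z, m))^2)
  names(m) <- names(b) <- colnames(y)
  lipid_body <- m[increasing] / sum(m[increasing])
  structure(list(
    m = m, b = b, x0 = x0, increasing = stats::setNames(increasing, colnames(y)),
    rss = rss,
    lean_composition = if (sum(b) > 0) b / sum(b) else b,
    lipid_body_composition = lipid_body,
    slope_threshold = slope_threshold, t_threshold = t_threshold
  ), class = "fame_fit")
}

#' @export
print.fame_fit <- function(x, ...) {
  cat(sprintf("<fame_fit> x0 = %.3f wt%% CDW, %d/%d fatty acids increasing, RSS = %.4g\n",
              x$x0, sum(x$increasing), length(x$m), x$rss))
  print(data.frame(slope_m = round(x$m, 4), intercept_b = round(x$b, 4),
                   increasing = x$increasing))
  invisible(x)
}

#' Abundance-weighted monomer composition
#'
#' Averages per-entity monomer compositions (e.g. amino-acid compositions
#' of proteins, base compositions of transcripts) weighted by measured
#' abundances (proteomics/transcriptomics), the standard way experimental
#' data updates a biomass macromolecule composition.
#'
#' @param entities named list: entity id -> named numeric vector of
#'   monomer mol fractions (each summing to 1).
#' @param weights named numeric vector: entity id -> abundance (>= 0, not
#'   all zero).
#' @return named numeric vector of monomer mol fractions, summing to 1.
#' @export
composition_from_weights <- function(entities, weights) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("weights must not be all zero")
  missing <- setdiff(names(weights)[weights > 0], names(entities))
  if (length(missing) > 0L) {
    stop("weighted entity without composition: ",
         paste(missing, collapse = ", "))
  }
  acc <- numeric(0)
  for (id in names(weights)) {
    if (weights[[id]] == 0) next
    comp <- entities[[id]]
    for (mn in names(comp)) {
      acc[mn] <- (if (mn %in% names(acc)) acc[[mn]] else 0) +
        weights[[id]] * comp[[mn]]
    }
  }
  acc / sum(acc)
}

#' Biomass composition specification
#'
#' Macromolecule mass fractions (g/gDW, summing to 1), per-macromolecule
#' monomer compositions (mol fractions, each summing to 1), monomer
#' metabolite ids and polymerized residue masses, and growth-associated
#' maintenance ATP.
#'
#' @param macromolecules named numeric vector of mass fractions (g/gDW).
#' @param monomers named list (per macromolecule) of data.frames with
#'   columns `metabolite`, `mol_fraction`, `residue_mass` (g/mmol); a
#'   macromolecule may instead map to `"lipid"` to be filled from a
#'   `fame_fit` by [assemble_biomass()].
#' @param gam growth-associated maintenance, mmol ATP/gDW.
#' @return a `biomass_spec`.
#' @export
biomass_spec <- function(macromolecules, monomers, gam = 30) {
  if (abs(sum(macromolecules) - 1) > 1e-4) {
    stop(sprintf("macromolecule mass fractions sum to %.6f, not 1 (tol 1e-4)",
                 sum(macromolecules)))
  }
  for (nm in names(monomers)) {
    mo <- monomers[[nm]]
    if (is.character(mo)) next
    if (abs(sum(mo$mol_fraction) - 1) > 1e-6) {
      stop(sprintf("monomer composition of '%s' sums to %.8f, not 1", nm,
                   sum(mo$mol_fraction)))
    }
  }
  structure(list(macromolecules = macromolecules, monomers = monomers,
                 gam = gam), class = "biomass_spec")
}

#' Assemble the biomass reaction and lipid-droplet demand/sink wiring
#'
#' Builds a biomass pseudo-reaction whose coefficients (mmol/gDW) are
#' `mass_fraction * mol_fraction / residue_mass` per monomer, plus
#' growth-associated maintenance ATP hydrolysis.  The lean fatty-acid
#' composition of a [fit_segmented()] fit fills the macromolecule slot
#' marked `"lipid"`.  Separately, irreversible demand reactions for
#' lipid-droplet triacylglycerol and sterol-ester accumulation are added
#' with stoichiometry proportional to the fitted lipid-body composition
#' `m_k`, and matching sink reactions (closed by default) allow simulating
#' mobilization.  The assembled biomass drains exactly 1 g/gDW (audited
#' to 1e-4).
#'
#' @param model a `metabolic_model` containing every monomer metabolite.
#' @param spec a `biomass_spec`.
#' @param fit a `fame_fit`; required when the spec has a `"lipid"` slot or
#'   lipid-body species are declared.
#' @param lipid_species named list mapping fitted fatty-acid names to
#'   model metabolite ids for the lean (free fatty-acid) species, e.g.
#'   `list(C16_0 = "hdca_c", ...)`.
#' @param tag_species named character vector mapping increasing fatty
#'   acids to lipid-droplet triacylglycerol metabolite ids.
#' @param se_species optional sterol-ester metabolite id (gets its own
#'   demand/sink).
#' @param biomass_id,atp,adp,pi,h2o,h ids used for the biomass reaction
#'   and the maintenance hydrolysis.
#' @return the model with `biomass_id`, `DM_*` and `SK_*` reactions added
#'   and the objective set to biomass.
#' @export
assemble_biomass <- function(model, spec, fit = NULL,
                             lipid_species = NULL, tag_species = NULL,
                             se_species = NULL,
                             biomass_id = "BIOMASS",
                             atp = "atp_c", adp = "adp_c", pi = "pi_c",
                             h2o = "h2o_c", h = "h_c") {
  stopifnot(inherits(spec, "biomass_spec"))
  st <- numeric(0)
  drain <- function(st, met, mmol) {
    if (!met %in% model$metabolites$id) {
      stop(sprintf("biomass monomer metabolite '%s' missing from model", met))
    }
    st[met] <- (if (met %in% names(st)) st[[met]] else 0) - mmol
    st
  }
  total_mass <- 0
  for (nm in names(spec$macromolecules)) {
    frac <- spec$macromolecules[[nm]]
    mo <- spec$monomers[[nm]]
    if (is.null(mo)) stop(sprintf("no monomer table for macromolecule '%s'", nm))
    if (is.character(mo) && mo == "lipid") {
      if (is.null(fit) || is.null(lipid_species)) {
        stop("a fame_fit and lipid_species mapping are required for the lipid slot")
      }
      comp <- fit$lean_composition
      mo <- data.frame(
        metabolite = vapply(names(comp), function(k) {
          id <- lipid_species[[k]]
          if (is.null(id)) stop(sprintf("no model species for fatty acid '%s'", k))
          id
        }, character(1)),
        mass_fraction = as.numeric(comp),
        stringsAsFactors = FALSE)
      # lean lipid composition is mass-based: convert to per-monomer mmol
      for (i in seq_len(nrow(mo))) {
        mm <- met_residue_mass(model, mo$metabolite[i])
        mmol <- frac * mo$mass_fraction[i] / mm
        st <- drain(st, mo$metabolite[i], mmol)
        total_mass <- total_mass + mmol * mm
      }
      next
    }
    for (i in seq_len(nrow(mo))) {
      mmol <- frac * mo$mol_fraction[i] / mo$residue_mass[i]
      st <- drain(st, mo$metabolite[i], mmol)
      total_mass <- total_mass + mmol * mo$residue_mass[i]
    }
  }
  if (abs(total_mass - 1) > 1e-4) {
    stop(sprintf("assembled biomass drains %.6f g/gDW, not 1 (tol 1e-4)",
                 total_mass))
  }
  # growth-associated maintenance: mass-neutral ATP hydrolysis
  if (spec$gam > 0) {
    st <- drain(st, atp, spec$gam)
    st <- drain(st, h2o, spec$gam)
    st[adp] <- (if (adp %in% names(st)) st[[adp]] else 0) + spec$gam
    st[pi] <- (if (pi %in% names(st)) st[[pi]] else 0) + spec$gam
    st[h] <- (if (h %in% names(st)) st[[h]] else 0) + spec$gam
  }
  if (biomass_id %in% names(model$reactions)) {
    model <- remove_reactions(model, biomass_id)
  }
  model <- add_reaction(model, biomass_id, st, lower_bound = 0,
                        upper_bound = 1000, name = "biomass (lean cell mass)",
                        kind = "biomass")
  model <- set_objective(model, biomass_id)
  # lipid-droplet accumulation demands and mobilization sinks
  if (!is.null(fit) && !is.null(tag_species)) {
    mk <- fit$lipid_body_composition
    missing_fa <- setdiff(names(mk), names(tag_species))
    if (length(missing_fa) > 0L) {
      stop("no triacylglycerol species for increasing fatty acid(s): ",
           paste(missing_fa, collapse = ", "))
    }
    ids <- tag_species[names(mk)]
    # per 1 g of lipid body: coefficients proportional to m_k
    mbar <- sum(mk * vapply(ids, function(i) met_residue_mass(model, i),
                            numeric(1)))
    coefs <- as.numeric(mk) * (1 / mbar)
    dm_st <- stats::setNames(-coefs, ids)
    for (rid in c("DM_tag_lipid_body", "SK_tag_lipid_body")) {
      if (rid %in% names(model$reactions)) model <- remove_reactions(model, rid)
    }
    model <- add_reaction(model, "DM_tag_lipid_body", dm_st,
                          lower_bound = 0, upper_bound = 1000,
                          name = "triacylglycerol accumulation in lipid droplet",
                          kind = "demand")
    model <- add_reaction(model, "SK_tag_lipid_body", dm_st,
                          lower_bound = 0, upper_bound = 0,
                          name = "triacylglycerol mobilization from lipid droplet",
                          kind = "sink")
  }
  if (!is.null(se_species)) {
    se_st <- stats::setNames(-1 / met_residue_mass(model, se_species),
                             se_species)
    for (rid in c("DM_se_lipid_body", "SK_se_lipid_body")) {
      if (rid %in% names(model$reactions)) model <- remove_reactions(model, rid)
    }
    model <- add_reaction(model, "DM_se_lipid_body", se_st,
                          lower_bound = 0, upper_bound = 1000,
                          name = "sterol-ester accumulation in lipid droplet",
                          kind = "demand")
    model <- add_reaction(model, "SK_se_lipid_body", se_st,
                          lower_bound = 0, upper_bound = 0,
                          name = "sterol-ester mobilization from lipid droplet",
                          kind = "sink")
  }
  model
}

# residue mass (g/mmol) of a model metabolite from its formula
met_residue_mass <- function(model, met_id) {
  f <- model$metabolites$formula[model$metabolites$id == met_id]
  if (length(f) == 0L || is.na(f)) {
    stop(sprintf("metabolite '%s' has no formula; cannot derive residue mass",
                 met_id))
  }
  molar_mass(f) / 1000
}

#' Audit the mass drained by a biomass reaction
#'
#' Sums `|coefficient| * molar mass` over the consumed metabolites of a
#' biomass reaction, excluding the mass-neutral maintenance hydrolysis
#' (ATP + H2O -> ADP + Pi + H contributes zero net mass because its
#' products reappear with opposite signs).
#'
#' @param model a `metabolic_model`.
#' @param biomass_id biomass reaction id.
#' @return drained mass in g/gDW (1 for a well-formed biomass).
#' @export
biomass_mass <- function(model, biomass_id = "BIOMASS") {
  r <- model$reactions[[biomass_id]]
  if (is.null(r)) stop(sprintf("no reaction '%s'", biomass_id))
  masses <- vapply(names(r$stoichiometry),
                   function(m) met_residue_mass(model, m), numeric(1))
  -sum(r$stoichiometry * masses)
}
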