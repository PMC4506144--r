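#' Simulate a multi-family language taxonomy
#'
#' Generates a classification table with the family > genus > language
#' hierarchy that [build_tree()] consumes. Counts may be fixed integers or
#' two-element ranges `c(min, max)` sampled uniformly per family/genus.
#'
#' @param n_families number of language families.
#' @param genera_per_family count or range of genera per family.
#' @param languages_per_genus count or range of languages per genus.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return data.frame with columns `family`, `genus`, `language_id`.
#' @export
simulate_taxonomy <- function(n_families = 15, genera_per_family = c(1, 4),
                              languages_per_genus = c(1, 5), seed = 1) {
  stopifnot(n_families >= 1, all(genera_per_family >= 1),
            all(languages_per_genus >= 1))
  pick <- function(spec) {
    if (length(spec) == 1) spec else sample(seq(spec[1], spec[2]), 1)
  }
  withr_seed(seed, {
    rows <- list()
    lang_counter <- 0L
    for (f in seq_len(n_families)) {
      n_gen <- pick(genera_per_family)
      for (g in seq_len(n_gen)) {
        n_lang <- pick(languages_per_genus)
        for (l in seq_len(n_lang)) {
          lang_counter <- lang_counter + 1L
          rows[[lang_counter]] <- data.frame(
            family = sprintf("F%02d", f),
            genus = sprintf("F%02d_g%02d", f, g),
            language_id = sprintf("L%04d", lang_counter),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}

# run expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# model covariance among tips for continuous trait models
trait_covariance <- function(tree, model = c("BM", "pagel_lambda", "OU"),
                             sigma2 = 1, lam = 1, alpha = 1) {
  model <- match.arg(model)
  v_bm <- ape::vcv(tree)
  switch(model,
    BM = sigma2 * v_bm,
    pagel_lambda = {
      v <- v_bm * lam
      diag(v) <- diag(v_bm)
      sigma2 * v
    },
    OU = {
      if (alpha <= 0) stop("OU needs alpha > 0")
      d <- patristic_matrix(tree)
      sigma2 / (2 * alpha) * exp(-alpha * d)
    }
  )
}

#' Simulate continuous traits on a tree
#'
#' Draws tip values from the multivariate normal distribution implied by the
#' chosen evolutionary model: Brownian motion (covariance = sigma2 x shared
#' path length), Pagel's lambda transform (off-diagonals scaled by lambda),
#' or a stationary Ornstein-Uhlenbeck process (covariance
#' `sigma2/(2 alpha) * exp(-alpha * patristic distance)`).
#'
#' @param tree a `"phylo"` object with positive depth.
#' @param model `"BM"`, `"pagel_lambda"` or `"OU"`.
#' @param sigma2 rate variance per year (>= 0).
#' @param lam signal scalar in `[0, 1]` (pagel_lambda model).
#' @param alpha reversion rate per year (> 0, OU model).
#' @param root_state trait value at the root (mean of the tip distribution).
#' @param n_replicates number of independent replicate draws.
#' @param seed integer RNG seed.
#' @return matrix of tip values, `n_replicates` rows, one column per tip
#'   (named by tip label).
#' @export
simulate_continuous_trait <- function(tree, model = "BM", sigma2 = 1,
                                      lam = 1, alpha = 1, root_state = 0,
                                      n_replicates = 1, seed = 1) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0,
            lam >= 0, lam <= 1, n_replicates >= 1)
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    out <- matrix(root_state, n_replicates, n)
    colnames(out) <- tree$tip.label
    return(out)
  }
  v <- trait_covariance(tree, model, sigma2, lam, alpha)
  cv <- chol(v)
  withr_seed(seed, {
    z <- matrix(stats::rnorm(n_replicates * n), n_replicates, n)
    out <- root_state + z %*% cv
    colnames(out) <- tree$tip.label
    out
  })
}

#' Simulate a binary trait on a tree
#'
#' Two generators: `"mk2"` evolves a two-state Markov chain down the tree
#' with gain rate `q01` and loss rate `q10` per year, drawing exact
#' exponential waiting times along each branch (safe for multifurcations);
#' `"threshold"` simulates a Brownian liability and dichotomises it at
#' `threshold`.
#'
#' @param tree a `"phylo"` object.
#' @param model `"mk2"` or `"threshold"`.
#' @param q01,q10 transition rates per year (mk2; >= 0).
#' @param sigma2 liability rate variance (threshold model).
#' @param threshold liability cut point (threshold model).
#' @param root_state state at the root: 0/1 for mk2, real liability for
#'   threshold.
#' @param seed integer RNG seed.
#' @return named integer vector of tip states in `{0, 1}`.
#' @export
simulate_binary_trait <- function(tree, model = c("mk2", "threshold"),
                                  q01 = 1e-5, q10 = 1e-5, sigma2 = 1,
                                  threshold = 0, root_state = 0, seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"))
  if (model == "threshold") {
    liab <- simulate_continuous_trait(tree, "BM", sigma2 = sigma2,
                                      root_state = root_state, seed = seed)
    x <- as.integer(liab[1, ] > threshold)
    names(x) <- tree$tip.label
    return(x)
  }
  if (q01 < 0 || q10 < 0) stop("rates must be non-negative")
  n_tip <- length(tree$tip.label)
  withr_seed(seed, {
    state <- integer(n_tip + tree$Nnode)
    root <- n_tip + 1L
    state[root] <- as.integer(root_state)
    po <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(po$edge))) {
      parent <- po$edge[e, 1]
      child <- po$edge[e, 2]
      len <- po$edge.length[e]
      s <- state[parent]
      t_left <- len
      repeat {
        rate <- if (s == 0) q01 else q10
        if (rate == 0) break
        wait <- stats::rexp(1, rate)
        if (wait > t_left) break
        t_left <- t_left - wait
        s <- 1L - s
      }
      state[child] <- s
    }
    x <- state[seq_len(n_tip)]
    names(x) <- tree$tip.label
    x
  })
}

#' Assemble per-language metadata for a synthetic scenario
#'
#' Combines a classification, a simulated binary trait (the strong/weak
#' future-time-reference class), simulated coordinates, and geographically
#' assigned linguistic areas and countries into the language table the
#' respondent simulator and the battery consume. Areas are longitude bands
#' (contact areas are geographic, cross-cutting families); countries are
#' spatial clusters of languages, so one country can host several languages
#' and crossed random effects are identifiable.
#'
#' @param classification output of [simulate_taxonomy()].
#' @param tree tree built from the classification.
#' @param ftr named 0/1 vector per language (1 = weak FTR).
#' @param coords data.frame with `language_id`, `latitude`, `longitude`.
#' @param n_areas,n_countries number of linguistic areas / countries.
#' @param seed integer RNG seed.
#' @return data.frame (`LanguageMeta`): `language_id`, `ftr`
#'   (`"strong"`/`"weak"`), `family`, `genus`, `area`, `country`,
#'   `latitude`, `longitude`, `population`.
#' @export
simulate_language_meta <- function(classification, tree, ftr, coords,
                                   n_areas = 6, n_countries = 20, seed = 1) {
  stopifnot(all(classification$language_id %in% coords$language_id))
  meta <- merge(classification, coords, by = "language_id", sort = TRUE)
  meta$ftr <- ifelse(ftr[meta$language_id] == 1, "weak", "strong")
  br <- stats::quantile(meta$longitude, probs = seq(0, 1, length.out = n_areas + 1))
  br[1] <- -Inf
  br[length(br)] <- Inf
  meta$area <- paste0("A", as.integer(cut(meta$longitude, unique(br))))
  withr_seed(seed, {
    k <- min(n_countries, nrow(meta))
    cl <- stats::kmeans(meta[, c("latitude", "longitude")], centers = k,
                        nstart = 3)
    meta$country <- sprintf("C%02d", cl$cluster)
    meta$population <- round(stats::rlnorm(nrow(meta), meanlog = 9, sdlog = 2))
  })
  meta[order(meta$language_id), ]
}

#' Simulate respondent-level survey data
#'
#' Draws `n_per_language` respondents per language. The binary outcome
#' (`saved`) comes from a logistic model with a fixed effect of weak FTR,
#' fixed covariate effects, and crossed random intercepts and random FTR
#' slopes for country, language family and linguistic area. Covariates are
#' Bernoulli by default: employment 0.6, sex (female) 0.5, trust 0.3.
#'
#' @param meta language table from [simulate_language_meta()] (needs
#'   `language_id`, `ftr`, `family`, `area`, `country`).
#' @param beta_ftr logit effect of speaking a weak-FTR language.
#' @param beta_covariates named numeric vector of logit effects for
#'   `employed`, `sex_female`, `trust` (any subset).
#' @param intercept logit intercept.
#' @param sd_country,sd_family,sd_area random-intercept SDs (>= 0).
#' @param sd_slope_country,sd_slope_family,sd_slope_area random-slope SDs.
#' @param n_per_language respondents per language (>= 1).
#' @param covariate_probs Bernoulli probabilities for the covariates.
#' @param seed integer RNG seed.
#' @return data.frame (`RespondentTable`): `respondent_id`, `saved`,
#'   `language_id`, `country`, `family`, `area`, `ftr`, `weak_ftr`,
#'   `employed`, `sex_female`, `trust`, `wave`.
#' @export
simulate_respondents <- function(meta, beta_ftr = 0, beta_covariates = NULL,
                                 intercept = 0, sd_country = 0,
                                 sd_family = 0, sd_area = 0,
                                 sd_slope_country = 0, sd_slope_family = 0,
                                 sd_slope_area = 0, n_per_language = 100,
                                 covariate_probs = c(employed = 0.6,
                                                     sex_female = 0.5,
                                                     trust = 0.3),
                                 seed = 1) {
  need <- c("language_id", "ftr", "family", "area", "country")
  if (!all(need %in% names(meta))) {
    stop("meta needs columns: ", paste(need, collapse = ", "))
  }
  stopifnot(n_per_language >= 1, sd_country >= 0, sd_family >= 0,
            sd_area >= 0, sd_slope_country >= 0, sd_slope_family >= 0,
            sd_slope_area >= 0)
  withr_seed(seed, {
    draw <- function(levels, sd) {
      stats::setNames(stats::rnorm(length(levels), 0, sd), levels)
    }
    b_country <- draw(unique(meta$country), sd_country)
    b_family <- draw(unique(meta$family), sd_family)
    b_area <- draw(unique(meta$area), sd_area)
    s_country <- draw(unique(meta$country), sd_slope_country)
    s_family <- draw(unique(meta$family), sd_slope_family)
    s_area <- draw(unique(meta$area), sd_slope_area)

    idx <- rep(seq_len(nrow(meta)), each = n_per_language)
    n <- length(idx)
    dat <- data.frame(
      respondent_id = sprintf("R%06d", seq_len(n)),
      language_id = meta$language_id[idx],
      country = meta$country[idx],
      family = meta$family[idx],
      area = meta$area[idx],
      ftr = meta$ftr[idx],
      stringsAsFactors = FALSE
    )
    dat$weak_ftr <- as.integer(dat$ftr == "weak")
    for (cv in names(covariate_probs)) {
      dat[[cv]] <- stats::rbinom(n, 1, covariate_probs[[cv]])
    }
    eta <- intercept + beta_ftr * dat$weak_ftr +
      b_country[dat$country] + b_family[dat$family] + b_area[dat$area] +
      (s_country[dat$country] + s_family[dat$family] + s_area[dat$area]) *
        dat$weak_ftr
    if (!is.null(beta_covariates)) {
      for (cv in names(beta_covariates)) {
        eta <- eta + beta_covariates[[cv]] * dat[[cv]]
      }
    }
    dat$saved <- stats::rbinom(n, 1, stats::plogis(eta))
    dat$wave <- sample(3:5, n, replace = TRUE)
    dat
  })
}

#' Simulate spatially structured coordinates by Brownian dispersal
#'
#' Locations diffuse down the tree: each edge displaces the position by a
#' normal step with standard deviation `dispersal_scale *
#' sqrt(edge_length / tree_depth)` km in each direction, so closely related
#' languages end up geographically closer in expectation. Kilometres are
#' converted to degrees with a `cos(latitude)` correction for longitude;
#' latitudes are clamped to `[-90, 90]`, longitudes wrapped to
#' `[-180, 180]`.
#'
#' @param tree a `"phylo"` object.
#' @param dispersal_scale dispersal SD in km over the full tree depth
#'   (>= 0).
#' @param root_location `c(latitude, longitude)` of the root.
#' @param seed integer RNG seed.
#' @return data.frame with `language_id`, `latitude`, `longitude`.
#' @export
simulate_coordinates <- function(tree, dispersal_scale = 5000,
                                 root_location = c(20, 40), seed = 1) {
  stopifnot(inherits(tree, "phylo"), dispersal_scale >= 0)
  n_tip <- length(tree$tip.label)
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth <= 0) depth <- 1
  withr_seed(seed, {
    lat <- numeric(n_tip + tree$Nnode)
    lon <- numeric(n_tip + tree$Nnode)
    root <- n_tip + 1L
    lat[root] <- root_location[1]
    lon[root] <- root_location[2]
    po <- ape::reorder.phylo(tree, "cladewise")
    km_per_deg <- 111.32
    for (e in seq_len(nrow(po$edge))) {
      parent <- po$edge[e, 1]
      child <- po$edge[e, 2]
      sd_km <- dispersal_scale * sqrt(po$edge.length[e] / depth)
      dlat_km <- stats::rnorm(1, 0, sd_km)
      dlon_km <- stats::rnorm(1, 0, sd_km)
      new_lat <- lat[parent] + dlat_km / km_per_deg
      new_lat <- max(-90, min(90, new_lat))
      coslat <- max(cos(new_lat * pi / 180), 0.01)
      new_lon <- lon[parent] + dlon_km / (km_per_deg * coslat)
      new_lon <- ((new_lon + 180) %% 360) - 180
      lat[child] <- new_lat
      lon[child] <- new_lon
    }
    data.frame(language_id = tree$tip.label,
               latitude = lat[seq_len(n_tip)],
               longitude = lon[seq_len(n_tip)],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete scenario for the battery
#'
#' One call that chains the generators: taxonomy, tree, binary FTR trait,
#' coordinates, language metadata and respondents. All defaults give a
#' scenario with phylogenetic signal in FTR, spatially clustered languages,
#' and respondent outcomes driven by crossed group effects. A YAML scenario
#' file (see [read_scenario()]) can override any argument.
#'
#' @param n_families,genera_per_family,languages_per_genus taxonomy spec.
#' @param family_depth,root_depth tree depths in years.
#' @param q01,q10 FTR gain/loss rates per year.
#' @param dispersal_scale coordinate dispersal in km.
#' @param beta_ftr,intercept,beta_covariates respondent model fixed effects.
#' @param sd_country,sd_family,sd_area,sd_slope_country,sd_slope_family,sd_slope_area
#'   random-effect SDs of the respondent model.
#' @param n_per_language respondents per language.
#' @param n_areas,n_countries metadata grouping sizes.
#' @param seed master seed; each generator gets an independent stream
#'   derived from it.
#' @return list with elements `classification`, `tree`, `ftr`, `coords`,
#'   `meta`, `respondents`, `seed`.
#' @export
simulate_scenario <- function(n_families = 15, genera_per_family = c(1, 4),
                              languages_per_genus = c(1, 5),
                              family_depth = 6000, root_depth = 60000,
                              q01 = 2e-5, q10 = 2e-5,
                              dispersal_scale = 6000,
                              beta_ftr = 0.4, intercept = -1.1,
                              beta_covariates = c(employed = 0.6,
                                                  sex_female = -0.11,
                                                  trust = 0.13),
                              sd_country = 0.5, sd_family = 0.3,
                              sd_area = 0.2, sd_slope_country = 0.1,
                              sd_slope_family = 0.1, sd_slope_area = 0.1,
                              n_per_language = 100, n_areas = 6,
                              n_countries = 20, seed = 1) {
  seeds <- derive_seeds(seed, 5)
  cls <- simulate_taxonomy(n_families, genera_per_family,
                           languages_per_genus, seed = seeds[1])
  tree <- build_tree(cls, family_depth = family_depth,
                     root_depth = root_depth)
  ftr <- simulate_binary_trait(tree, "mk2", q01 = q01, q10 = q10,
                               root_state = 0, seed = seeds[2])
  if (all(ftr == ftr[1])) { # guarantee both classes for downstream stages
    flip <- seq_len(max(1, length(ftr) %/% 4))
    ftr[flip] <- 1L - ftr[flip]
  }
  coords <- simulate_coordinates(tree, dispersal_scale, seed = seeds[3])
  meta <- simulate_language_meta(cls, tree, ftr, coords, n_areas = n_areas,
                                 n_countries = n_countries, seed = seeds[4])
  resp <- simulate_respondents(meta, beta_ftr = beta_ftr,
                               beta_covariates = beta_covariates,
                               intercept = intercept,
                               sd_country = sd_country,
                               sd_family = sd_family, sd_area = sd_area,
                               sd_slope_country = sd_slope_country,
                               sd_slope_family = sd_slope_family,
                               sd_slope_area = sd_slope_area,
                               n_per_language = n_per_language,
                               seed = seeds[5])
  list(classification = cls, tree = tree, ftr = ftr, coords = coords,
       meta = meta, respondents = resp, seed = seed)
}

# independent sub-stream seeds below 2^31, deterministic in the master seed
derive_seeds <- function(seed, n) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1, n))
}

#' Read a YAML scenario file
#'
#' Reads a YAML mapping of [simulate_scenario()] arguments and returns the
#' simulated scenario, making every generated dataset reproducible from a
#' text file.
#'
#' @param path YAML file path.
#' @return as [simulate_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(simulate_scenario, cfg)
}
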