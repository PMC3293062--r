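.indicators <- c("Testis_W", "Epidid_W", "SpC", "SpM", "MDA", "MPO",
                 "CAT", "SOD")

#' Built-in per-group indicator summary statistics
#'
#' Loads the shipped YAML file of group means and standard errors for the
#' eight fertility and oxidative-stress indicators (testis and epididymis
#' weight, sperm count and motility, MDA, MPO, CAT, SOD) across the six
#' study groups (N, GB, CIS, CIS+L, CIS+M, CIS+H), with n = 10 animals per
#' group.
#'
#' @param path optional path to an alternative YAML file with the same
#'   layout.
#' @return named list of group specs; each spec is a named list of
#'   `list(mean =, se =)` per indicator, with an `n_animals` attribute on
#'   the outer list.
#' @export
group_indicator_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "group_indicators.yaml",
                        package = "texclust", mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  specs <- y$groups
  for (g in names(specs)) {
    missing <- setdiff(.indicators, names(specs[[g]]))
    if (length(missing) > 0L) {
      stop("group ", g, " is missing indicator(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  attr(specs, "n_animals") <- if (is.null(y$n_animals)) 10L
                              else as.integer(y$n_animals)
  specs
}

#' Simulate per-animal indicator tables from group summary statistics
#'
#' For each group, draws `n_animals` independent animals; each indicator is
#' drawn as `Normal(mean, SD)` with `SD = SE * sqrt(n0)`, where `n0` is the
#' group size at which the standard errors were stated (the specs'
#' `n_animals` attribute, default 10) — so simulating extra animals for
#' calibration does not inflate the per-animal spread. Indicators are
#' drawn independently of one another. `spread = "sd"` instead
#' treats the stated error terms as standard deviations directly. Negative
#' draws of these strictly positive quantities are truncated at 0 with a
#' warning. Deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param specs group specs as returned by [group_indicator_specs()];
#'   subset the list to simulate fewer groups.
#' @param n_animals animals per group (default: the specs' stated group
#'   size, 10).
#' @param seed integer RNG seed.
#' @param spread whether the stated error terms are standard errors
#'   (`"se"`, default) or standard deviations (`"sd"`).
#' @return a feature table: `sample_id`, `group`, and the eight indicator
#'   columns.
#' @export
make_animal_table <- function(specs = group_indicator_specs(),
                              n_animals = NULL, seed = 1L,
                              spread = c("se", "sd")) {
  spread <- match.arg(spread)
  if (is.null(names(specs)) || anyDuplicated(names(specs))) {
    stop("'specs' must be a uniquely named list of group specs",
         call. = FALSE)
  }
  n0 <- attr(specs, "n_animals")
  if (is.null(n0)) n0 <- 10L
  if (is.null(n_animals)) n_animals <- n0
  n_animals <- as.integer(n_animals)
  if (n_animals < 2L) stop("'n_animals' must be at least 2", call. = FALSE)
  for (g in names(specs)) {
    missing <- setdiff(.indicators, names(specs[[g]]))
    if (length(missing) > 0L) {
      stop("group ", g, " is missing indicator(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  withr::with_seed(as.integer(seed), {
    rows <- lapply(names(specs), function(g) {
      vals <- vapply(.indicators, function(ind) {
        m <- specs[[g]][[ind]]$mean
        e <- specs[[g]][[ind]]$se
        s <- if (spread == "se") e * sqrt(n0) else e
        if (s == 0) rep(m, n_animals) else rnorm(n_animals, m, s)
      }, numeric(n_animals))
      if (n_animals == 1L) vals <- matrix(vals, nrow = 1L,
                                          dimnames = list(NULL, .indicators))
      data.frame(sample_id = sprintf("%s_%02d", g, seq_len(n_animals)),
                 group = g, vals, check.names = FALSE,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    out <- do.call(rbind, rows)
    neg <- vapply(.indicators, function(ind) sum(out[[ind]] < 0), integer(1))
    if (any(neg > 0)) {
      warning("truncated ", sum(neg),
              " negative draw(s) at 0 for positive quantities: ",
              paste(.indicators[neg > 0], collapse = ", "), call. = FALSE)
      for (ind in .indicators) out[[ind]] <- pmax(out[[ind]], 0)
    }
    out
  })
}
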