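# Shared fixtures, built in code.

# One- or multi-country synthetic spec with a single cause profile.
tiny_spec <- function(profile, cause = "I", seed = 1L,
                      countries = list(list(name = "Alpha",
                                            years = 2000:2001,
                                            pop_under1 = 4e5,
                                            pop_band = 4e5)),
                      grid = standard_age_grid(10), ...) {
  profiles <- list(profile)
  names(profiles) <- cause
  synthetic_spec(countries, profiles, grid = grid, seed = seed, ...)
}

# Hand-built death-count table (plain data frame; the loaders attach the
# class but the computational functions only need the columns).
manual_deaths <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df[, c("country", "year", "cause", "age_label", "deaths")]
}

# Population table covering every band of a grid with constant counts.
manual_pop <- function(country, years, under1, per_band,
                       grid = standard_age_grid(10)) {
  bands <- c("under-1", grid$label[grid$band == "whole_year"])
  do.call(rbind, lapply(years, function(y) {
    data.frame(country = country, year = y, age_band = bands,
               count = c(under1, rep(per_band, length(bands) - 1L)),
               stringsAsFactors = FALSE)
  }))
}

# Log-log points straight from (x, mu) vectors.
points_from_rates <- function(x, mu) {
  structure(data.frame(label = as.character(seq_along(x)), x = x,
                       lnx = log(x), lnmu = log(mu),
                       stringsAsFactors = FALSE),
            class = c("loglog_points", "data.frame"))
}

# Independent OLS oracle: closed-form normal equations for y on columns X.
ols_oracle <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  list(beta = as.vector(beta), rss = sum(res^2))
}
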