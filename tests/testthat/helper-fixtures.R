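# Hand-built fixtures shared across test files.

# one composition row with zero defaults; extra named args must be
# composition columns
make_food <- function(code, energy = 0, protein = 0, carb = 0, fat = 0,
                      sfa = 0, mufa = 0, pufa = 0, dairy_fat = 0, ...) {
  row <- as.list(stats::setNames(numeric(length(composition_columns())),
                                 composition_columns()))
  row$energy_kcal <- energy; row$protein_g <- protein; row$carb_g <- carb
  row$fat_g <- fat; row$sfa_g <- sfa; row$mufa_g <- mufa; row$pufa_g <- pufa
  row$dairy_fat_g <- dairy_fat
  extra <- list(...)
  stopifnot(all(names(extra) %in% composition_columns()))
  row[names(extra)] <- extra
  cbind(data.frame(food_code = code, stringsAsFactors = FALSE),
        as.data.frame(row))
}

make_food_db <- function(...) do.call(rbind, list(...))

# named totals vector over all composition columns
make_totals <- function(...) {
  tot <- stats::setNames(numeric(length(composition_columns())),
                         composition_columns())
  extra <- list(...)
  stopifnot(all(names(extra) %in% names(tot)))
  tot[names(extra)] <- unlist(extra)
  tot
}

# a small generated study dataset, cached per session
small_synthetic <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_participants = 250, seed = 11)
      db <- generate_food_database(cfg)
      pop <- generate_population(cfg)
      ints <- generate_recalls(pop, db, cfg)
      foods <- suppressWarnings(add_dairy_fat(db$foods, db$recipes,
                                              db$ingredients))
      cache <<- list(cfg = cfg, db = db, pop = pop, ints = ints,
                     foods = foods,
                     metrics = suppressMessages(derive_food_metrics(foods)))
    }
    cache
  }
})
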