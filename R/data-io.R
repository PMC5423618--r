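#' @importFrom rlang .data
NULL

height_cols <- c("individual_id", "species", "ecosystem", "age_yrs", "height_cm")
trait_cols <- c("species", "ecosystem", "sla", "wood_density", "seed_mass", "leaf_n")

#' Names of the functional traits handled by the package
#' @return Character vector: `sla`, `wood_density`, `seed_mass`, `leaf_n`.
#' @export
trait_names <- function() c("sla", "wood_density", "seed_mass", "leaf_n")

#' Read a table of individual height observations
#'
#' Expects a UTF-8 CSV with a header row and columns `individual_id`,
#' `species`, `ecosystem`, `age_yrs` (years since fire) and `height_cm`.
#' Rows violating the invariants (non-positive height, negative age, missing
#' values, duplicated `(individual_id, ecosystem)`) are reported with their
#' row numbers; nothing is silently repaired.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated height records.
#' @export
read_heights <- function(path) {
  df <- read_table_checked(path, height_cols)
  validate_heights(df)
}

#' Read a species trait table
#'
#' Expects a CSV with columns `species`, `ecosystem`, `sla`, `wood_density`,
#' `seed_mass`, `leaf_n`; one row per `(species, ecosystem)`. All trait
#' values must be finite and strictly positive.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated trait records.
#' @export
read_traits <- function(path) {
  df <- read_table_checked(path, trait_cols)
  validate_traits(df)
}

#' Write height / trait tables
#'
#' Plain-CSV writers matching [read_heights()] and [read_traits()], so a
#' read-write-read round trip is lossless for valid files.
#'
#' @param x A height or trait tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heights <- function(x, path) {
  readr::write_csv(validate_heights(x)[height_cols], path)
  invisible(path)
}

#' @rdname write_heights
#' @export
write_traits <- function(x, path) {
  readr::write_csv(validate_traits(x)[trait_cols], path)
  invisible(path)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "Format error in %s: missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(df) == 0) warning(sprintf("%s contains a header but no data rows.", basename(path)))
  tibble::as_tibble(df)
}

#' Validate a height table
#'
#' @param heights A data frame with the height-record columns.
#' @return The input as a tibble (unmodified) if valid; otherwise an error
#'   listing every offending row number.
#' @export
validate_heights <- function(heights) {
  heights <- tibble::as_tibble(heights)
  assert_has_cols(heights, height_cols, "height table")
  problems <- character(0)
  bad <- which(!is.finite(heights$height_cm) | heights$height_cm <= 0)
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "non-positive or missing height_cm in row(s): %s", row_list(bad)
    ))
  }
  bad <- which(!is.finite(heights$age_yrs) | heights$age_yrs < 0)
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "negative or missing age_yrs in row(s): %s", row_list(bad)
    ))
  }
  bad <- which(is.na(heights$individual_id) | is.na(heights$species) |
    is.na(heights$ecosystem))
  if (length(bad)) {
    problems <- c(problems, sprintf("missing identifier(s) in row(s): %s", row_list(bad)))
  }
  key <- paste(heights$individual_id, heights$ecosystem, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "duplicated (individual_id, ecosystem) in row(s): %s", row_list(bad)
    ))
  }
  if (length(problems)) {
    stop(paste0("Invalid height records:\n  - ", paste(problems, collapse = "\n  - ")),
      call. = FALSE
    )
  }
  heights
}

#' Validate a trait table
#'
#' @param traits A data frame with the trait-record columns.
#' @return The input as a tibble if valid, else an error naming the species.
#' @export
validate_traits <- function(traits) {
  traits <- tibble::as_tibble(traits)
  assert_has_cols(traits, trait_cols, "trait table")
  problems <- character(0)
  key <- paste(traits$species, traits$ecosystem, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(traits$species[duplicated(key)])
    problems <- c(problems, sprintf(
      "duplicated (species, ecosystem) record(s) for: %s", paste(dups, collapse = ", ")
    ))
  }
  for (tr in trait_names()) {
    v <- traits[[tr]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "non-positive or missing %s for species: %s",
        tr, paste(unique(traits$species[bad]), collapse = ", ")
      ))
    }
  }
  if (length(problems)) {
    stop(paste0("Invalid trait records:\n  - ", paste(problems, collapse = "\n  - ")),
      call. = FALSE
    )
  }
  traits
}

#' Bundle heights and traits into a validated dataset
#'
#' Joins the two tables of a chronosequence study into one object, checking
#' the cross-table invariants: every species appearing among the heights must
#' have a trait record in the same ecosystem, and each species needs at least
#' two distinct observation ages for the sigmoid to be identifiable. Species
#' failing the age requirement are flagged with a warning and recorded in the
#' `underidentified` field; they are not silently fitted.
#'
#' @param heights A height table (see [read_heights()]).
#' @param traits A trait table (see [read_traits()]).
#' @return An object of class `growth_data`: a list with tibbles `heights`
#'   and `traits`, the character vector `ecosystems`, and `underidentified`
#'   (species with fewer than two distinct ages).
#' @export
growth_data <- function(heights, traits) {
  heights <- validate_heights(heights)
  traits <- validate_traits(traits)
  hkey <- unique(paste(heights$species, heights$ecosystem, sep = "\r"))
  tkey <- paste(traits$species, traits$ecosystem, sep = "\r")
  orphan <- setdiff(hkey, tkey)
  if (length(orphan)) {
    stop(sprintf(
      "Species without a trait record in their ecosystem: %s",
      paste(sub("\r", " @ ", orphan), collapse = ", ")
    ), call. = FALSE)
  }
  n_ages <- heights |>
    dplyr::distinct(.data$species, .data$ecosystem, .data$age_yrs) |>
    dplyr::count(.data$species, .data$ecosystem)
  under <- n_ages$species[n_ages$n < 2]
  if (length(under)) {
    warning(sprintf(
      "Species with fewer than 2 distinct ages (sigmoid unidentifiable): %s",
      paste(under, collapse = ", ")
    ))
  }
  structure(
    list(
      heights = heights,
      traits = traits,
      ecosystems = sort(unique(c(heights$ecosystem, traits$ecosystem))),
      underidentified = under
    ),
    class = "growth_data"
  )
}

#' @export
print.growth_data <- function(x, ...) {
  cat(sprintf(
    "<growth_data> %d height observations, %d species, %d ecosystem(s): %s\n",
    nrow(x$heights), nrow(x$traits), length(x$ecosystems),
    paste(x$ecosystems, collapse = ", ")
  ))
  if (length(x$underidentified)) {
    cat("  underidentified species:", paste(x$underidentified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a growth_data object to one ecosystem
#' @param data A `growth_data` object.
#' @param ecosystem Ecosystem identifier.
#' @return A `growth_data` object restricted to that ecosystem.
#' @export
filter_ecosystem <- function(data, ecosystem) {
  stopifnot(inherits(data, "growth_data"))
  if (!ecosystem %in% data$ecosystems) {
    stop(sprintf("Ecosystem '%s' not present in the dataset.", ecosystem), call. = FALSE)
  }
  suppressWarnings(growth_data(
    dplyr::filter(data$heights, .data$ecosystem == !!ecosystem),
    dplyr::filter(data$traits, .data$ecosystem == !!ecosystem)
  ))
}

#' Compute trait standardization statistics from a training trait table
#'
#' Records, per trait, the training mean and standard deviation (optionally
#' after a log transform), together with the ecosystem(s) they came from.
#' New-ecosystem traits must always be standardized with *training*
#' statistics, never their own; keeping the statistics as a first-class
#' object makes that explicit.
#'
#' @param traits A validated trait table.
#' @param log_traits Character vector of trait names to log-transform before
#'   centering and scaling (none by default; seed mass is a common choice).
#' @return A tibble of class `trait_stats` with columns `trait`, `mean`,
#'   `sd`, `log_transformed`, and attribute `provenance`.
#' @export
trait_stats <- function(traits, log_traits = character(0)) {
  traits <- validate_traits(traits)
  bad <- setdiff(log_traits, trait_names())
  if (length(bad)) {
    stop(sprintf("Unknown trait(s) in `log_traits`: %s", paste(bad, collapse = ", ")),
      call. = FALSE
    )
  }
  stats_tbl <- purrr::map_dfr(trait_names(), function(tr) {
    v <- traits[[tr]]
    if (tr %in% log_traits) v <- log(v)
    tibble::tibble(
      trait = tr, mean = mean(v), sd = stats::sd(v),
      log_transformed = tr %in% log_traits
    )
  })
  if (any(!is.finite(stats_tbl$sd) | stats_tbl$sd == 0)) {
    degenerate <- stats_tbl$trait[!is.finite(stats_tbl$sd) | stats_tbl$sd == 0]
    stop(sprintf(
      "Degenerate training trait(s) (zero or undefined sd): %s",
      paste(degenerate, collapse = ", ")
    ), call. = FALSE)
  }
  structure(stats_tbl,
    provenance = sort(unique(traits$ecosystem)),
    class = c("trait_stats", class(stats_tbl))
  )
}

#' Standardize traits with training statistics
#'
#' Maps each trait value x to `(x - mean_train) / sd_train` (on the log scale
#' for traits the statistics flag as log-transformed). Values outside the
#' training range produce z-scores beyond the training range — extrapolation
#' is allowed and never clipped.
#'
#' @param traits A validated trait table (any ecosystem).
#' @param stats A `trait_stats` object from the training data.
#' @return A tibble `species`, `ecosystem`, plus one standardized column per
#'   trait (same names as the raw traits).
#' @export
standardize_traits <- function(traits, stats) {
  traits <- validate_traits(traits)
  stopifnot(inherits(stats, "trait_stats"))
  out <- traits[c("species", "ecosystem")]
  for (i in seq_len(nrow(stats))) {
    tr <- stats$trait[i]
    v <- traits[[tr]]
    if (stats$log_transformed[i]) v <- log(v)
    out[[tr]] <- (v - stats$mean[i]) / stats$sd[i]
  }
  out
}

#' Invert trait standardization
#'
#' @param z_traits A standardized trait table from [standardize_traits()].
#' @param stats The `trait_stats` used to standardize.
#' @return A trait tibble on the original measurement scale.
#' @export
unstandardize_traits <- function(z_traits, stats) {
  stopifnot(inherits(stats, "trait_stats"))
  out <- z_traits[c("species", "ecosystem")]
  for (i in seq_len(nrow(stats))) {
    tr <- stats$trait[i]
    v <- z_traits[[tr]] * stats$sd[i] + stats$mean[i]
    if (stats$log_transformed[i]) v <- exp(v)
    out[[tr]] <- v
  }
  out
}

assert_has_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf(
      "Format error: %s is missing column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

row_list <- function(idx) paste(idx, collapse = ", ")
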