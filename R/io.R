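#' Write a data frame as CSV with a provenance header
#'
#' Comma-separated, '.' decimal, with `#`-prefixed metadata lines
#' (package version, seed, config hash) so every output records how to
#' regenerate it.
#'
#' @param x data frame.
#' @param path output file.
#' @param meta named character/numeric vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_csv_provenance <- function(x, path, meta = c()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("oncotip"))
  writeLines(sprintf("# oncotip %s", ver), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a provenance-headered CSV
#'
#' @param path file written by [write_csv_provenance()] (or any CSV whose
#'   comment lines start with `#`).
#' @return data frame; the header lines are attached as attribute
#'   `"meta"`.
#' @export
read_csv_provenance <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  attr(df, "meta") <- meta
  df
}

#' Read a tumour time-series CSV
#'
#' Expects columns `day`, `size` and optionally `replicate`; a header
#' line `# size_unit: mm3|cm3|cells` declares the unit (default cells).
#' Sizes are converted to cells on read.
#'
#' @param path CSV file.
#' @return data frame in cells, with attribute `unit` (the file's unit).
#' @export
read_tumour_csv <- function(path) {
  df <- read_csv_provenance(path)
  stopifnot(all(c("day", "size") %in% names(df)))
  meta <- attr(df, "meta")
  unit <- "cells"
  m <- grep("size_unit:", meta, value = TRUE)
  if (length(m)) unit <- trimws(sub(".*size_unit:", "", m[1]))
  if (!unit %in% c("cells", "cm3", "mm3"))
    stop(sprintf("unknown size_unit '%s'", unit))
  if (unit != "cells") df$size <- volume_to_cells(df$size, unit)
  attr(df, "unit") <- unit
  df
}

#' Write a tumour time-series CSV
#'
#' @param data data frame with `day`, `size` (cells) and optionally
#'   `replicate`.
#' @param path output file.
#' @param unit unit to write sizes in.
#' @param seed optional seed recorded in the header.
#' @export
write_tumour_csv <- function(data, path, unit = "cells", seed = NULL) {
  out <- data
  if (unit != "cells") out$size <- cells_to_volume(out$size, unit)
  meta <- c(size_unit = unit)
  if (!is.null(seed)) meta <- c(meta, seed = seed)
  write_csv_provenance(out, path, meta)
}

#' Read an age-specific incidence table CSV
#'
#' Columns `age_lo`, `age_hi`, `rate_per_100k_person_years` (registry
#' convention); rates are converted to per person-year.
#'
#' @param path CSV file.
#' @return data frame with `age_lo`, `age_hi`, `rate` (per person-year).
#' @export
read_incidence_csv <- function(path) {
  df <- read_csv_provenance(path)
  stopifnot(all(c("age_lo", "age_hi", "rate_per_100k_person_years") %in% names(df)))
  data.frame(age_lo = df$age_lo, age_hi = df$age_hi,
             rate = df$rate_per_100k_person_years / 1e5)
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, rejects unknown keys (naming the
#' offending key path), validates ranges, fills defaults and normalizes
#' units (`life_expectancy_years` and ages stay in years; the model
#' converts to days internally with 1 year = 365 days).
#'
#' Recognized blocks: `growth` (`model`, `nu`, `r`, `mu`, `gamma`, `s`,
#' or the alternative `r`, `A`, `K` threshold parameterization for
#' `erm1`/`erm2`), `mutation` (`n`, `p0`, `delta_percent`,
#' `life_expectancy_years`), `immune` (`case`, `s_min`, `s_max`, cycle
#' and menopause settings), `risk` (`n_women`, `horizon_years`,
#' `age_cut`), plus top-level `seed`, `out_dir`, `log_level`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a validated config list; growth/mutation/immune blocks are
#'   realized as the corresponding parameter objects under `growth`,
#'   `mutation`, `immune`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  # YAML 1.1 leaves exponent forms like 1.0e6 (no sign) as strings
  raw <- rapply(raw, function(x) {
    if (is.character(x) && length(x) == 1 &&
        grepl("^[+-]?[0-9.]+([eE][+-]?[0-9]+)?$", x)) as.numeric(x) else x
  }, how = "replace")
  known_top <- c("growth", "mutation", "immune", "risk", "fit",
                 "seed", "out_dir", "log_level")
  check_keys(raw, known_top, "")
  cfg <- list()
  if (!is.null(raw$growth)) cfg$growth <- parse_growth_block(raw$growth)
  if (!is.null(raw$mutation)) cfg$mutation <- parse_mutation_block(raw$mutation)
  if (!is.null(raw$immune)) {
    im <- raw$immune
    check_keys(im, c("case", "menarche_age", "luteal_days", "follicular_mean",
                     "follicular_sd", "fixed_follicular_days",
                     "menopause_mean", "menopause_sd", "hrt_fraction",
                     "hrt_mode", "hrt_sd", "s_min", "s_max"), "immune.")
    if (is.null(im$s_min) || is.null(im$s_max))
      stop("config error: immune.s_min and immune.s_max are required")
    cfg$immune <- immune_params(im$s_min, im$s_max,
                                hrt_fraction = im$hrt_fraction %||% 0.26,
                                hrt_mode = im$hrt_mode %||% 6,
                                hrt_sd = im$hrt_sd %||% 4.8)
    cfg$case <- im$case %||% 1
    if (!cfg$case %in% 0:3) stop("config error: immune.case must be 0, 1, 2 or 3")
    cfg$life_history_args <- list(
      menarche_age = im$menarche_age %||% 12,
      luteal_days = im$luteal_days %||% 14,
      follicular_mean = im$follicular_mean %||% 14,
      follicular_sd = im$follicular_sd %||% 2.4,
      menopause_mean = im$menopause_mean %||% 51,
      menopause_sd = im$menopause_sd %||% 4.86)
    cfg$fixed_follicular_days <- im$fixed_follicular_days
  }
  if (!is.null(raw$risk)) {
    check_keys(raw$risk, c("n_women", "horizon_years", "age_cut"), "risk.")
    cfg$risk <- raw$risk
  }
  cfg$horizon_years <- raw$risk$horizon_years %||% 85
  cfg$seed <- raw$seed %||% 1
  cfg$out_dir <- raw$out_dir %||% "."
  cfg
}

check_keys <- function(block, known, prefix) {
  extra <- setdiff(names(block), known)
  if (length(extra))
    stop(sprintf("config error: unknown key(s) %s",
                 paste0(prefix, extra, collapse = ", ")))
}

parse_growth_block <- function(g) {
  check_keys(g, c("model", "nu", "r", "mu", "gamma", "s", "A", "K"), "growth.")
  if (is.null(g$model)) stop("config error: growth.model is required")
  if (is.null(g$r) || g$r <= 0)
    stop("config error: growth.r must be a positive rate")
  nu <- g$nu %||% 1
  if (!is.null(g$A) && !is.null(g$K)) {
    if (g$model == "erm1") return(erm1_params_from_AK(g$r, g$A, g$K, nu = nu))
    if (g$model == "erm2") return(erm2_params_for_AK(g$r, g$A, g$K, nu = nu))
    stop("config error: growth.A/growth.K only apply to erm1 or erm2")
  }
  growth_params(g$model, nu = nu, r = g$r, mu = g$mu %||% 0,
                gamma = g$gamma, s = g$s)
}

parse_mutation_block <- function(m) {
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(m)[names(m) == "FALSE"] <- "n"
  check_keys(m, c("n", "p0", "delta_percent", "life_expectancy_years"),
             "mutation.")
  if (is.null(m$n) || is.null(m$p0))
    stop("config error: mutation.n and mutation.p0 are required")
  mutation_params(m$n, m$p0, delta = m$delta_percent %||% 0,
                  life_expectancy_years = m$life_expectancy_years %||% 80)
}

# small stable checksum for provenance headers (polynomial rolling hash;
# not cryptographic)
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
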