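## Delimited-text readers/writers for all scientific I/O (datasets here
## are tiny; transparency beats compactness) and the run-configuration
## reader. '#' starts a comment; header metadata lines are '# key: value'.

#' Read / write an NMRD profile
#'
#' Format: '#' comments, then a header line
#' `freq_MHz  temp_K  r1_mM_s  sigma` and whitespace-delimited rows.
#' Writing then reading returns the profile unchanged (lossless round
#' trip on the canonical sorted form).
#'
#' @param path file path.
#' @return [read_nmrd()]: an `nmrd_profile` data frame.
#' @export
read_nmrd <- function(path) {
  d <- .read_table_checked(path, c("freq_MHz", "temp_K", "r1_mM_s", "sigma"))
  if (any(d$freq_MHz <= 0))
    stop("frequencies must be > 0 (", path, ")", call. = FALSE)
  if (any(d$r1_mM_s < 0, na.rm = TRUE))
    stop("relaxivities must be >= 0 (", path, ")", call. = FALSE)
  d <- d[order(d$temp_K, d$freq_MHz), ]
  out <- data.frame(freq_MHz = d$freq_MHz, temp_K = d$temp_K,
                    r1 = d$r1_mM_s, sigma = d$sigma)
  rownames(out) <- NULL
  class(out) <- c("nmrd_profile", "data.frame")
  out
}

#' @rdname read_nmrd
#' @param profile an `nmrd_profile` data frame.
#' @param comment optional comment line(s) written at the top.
#' @export
write_nmrd <- function(profile, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  for (cm in comment) writeLines(paste("#", cm), con)
  writeLines("freq_MHz\ttemp_K\tr1_mM_s\tsigma", con)
  utils::write.table(
    data.frame(profile$freq_MHz, profile$temp_K, profile$r1, profile$sigma),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a variable-temperature 17O dataset
#'
#' Format: header `temp_K  R2r_s  dwr_rad_s  sigma_R2r  sigma_dwr`.
#' Temperatures must be strictly increasing.
#'
#' @param path file path.
#' @return [read_o17()]: an `o17_dataset` data frame.
#' @export
read_o17 <- function(path) {
  d <- .read_table_checked(path, c("temp_K", "R2r_s", "dwr_rad_s",
                                   "sigma_R2r", "sigma_dwr"))
  if (any(diff(d$temp_K) <= 0))
    stop("temperatures must be strictly increasing (", path, ")",
         call. = FALSE)
  out <- data.frame(temp_K = d$temp_K, R2r = d$R2r_s, dw_r = d$dwr_rad_s,
                    sigma_R2r = d$sigma_R2r, sigma_dwr = d$sigma_dwr)
  class(out) <- c("o17_dataset", "data.frame")
  out
}

#' @rdname read_o17
#' @param dataset an `o17_dataset` data frame.
#' @param comment optional comment line(s).
#' @export
write_o17 <- function(dataset, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  for (cm in comment) writeLines(paste("#", cm), con)
  writeLines("temp_K\tR2r_s\tdwr_rad_s\tsigma_R2r\tsigma_dwr", con)
  utils::write.table(
    data.frame(dataset$temp_K, dataset$R2r, dataset$dw_r,
               dataset$sigma_R2r, dataset$sigma_dwr),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a spectrum (field- or RF-swept)
#'
#' Two-column delimited text with '# key: value' metadata headers
#' (`mw_freq_GHz`, `temp_K`, `mode`, `B0_mT`, `kind`, ...). The abscissa
#' must be strictly increasing; violations are reported with the line
#' number.
#'
#' @param path file path.
#' @return [read_spectrum()]: an `epr_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- list()
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.+)$", h))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) trimws(m[3]) else val
    }
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body_idx)) stop("no data rows in ", path, call. = FALSE)
  vals <- lapply(body_idx, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                              "\\s+")[[1]]))
    if (length(v) != 2 || any(is.na(v)))
      stop("malformed spectrum row at line ", i, " of ", path,
           call. = FALSE)
    v
  })
  x <- vapply(vals, `[`, numeric(1), 1)
  y <- vapply(vals, `[`, numeric(1), 2)
  bad <- which(diff(x) <= 0)
  if (length(bad))
    stop("abscissa not strictly increasing at line ",
         body_idx[bad[1] + 1], " of ", path, call. = FALSE)
  kind <- if (identical(meta$kind, "rf")) "rf" else "field"
  meta$kind <- NULL
  if (!is.null(meta$mw_freq_GHz)) {
    meta$mw_freq_Hz <- meta$mw_freq_GHz * 1e9
    meta$mw_freq_GHz <- NULL
  }
  new_spectrum(x, y, kind = kind, metadata = meta)
}

#' @rdname read_spectrum
#' @param spectrum an `epr_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w"); on.exit(close(con))
  meta <- spectrum$metadata
  if (!is.null(meta$mw_freq_Hz)) {
    meta$mw_freq_GHz <- meta$mw_freq_Hz / 1e9
    meta$mw_freq_Hz <- NULL
  }
  meta$kind <- spectrum$kind
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 15)), con)
  utils::write.table(data.frame(spectrum$x, spectrum$y), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @noRd
.read_table_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no content in ", path, call. = FALSE)
  header <- strsplit(trimws(lines[keep[1]]), "\\s+")[[1]]
  if (!identical(header, cols))
    stop("bad header in ", path, ": expected '",
         paste(cols, collapse = " "), "'", call. = FALSE)
  rows <- keep[-1]
  if (!length(rows)) stop("no data rows in ", path, call. = FALSE)
  vals <- lapply(rows, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                              "\\s+")[[1]]))
    if (length(v) != length(cols))
      stop("malformed row at line ", i, " of ", path, call. = FALSE)
    v
  })
  d <- as.data.frame(do.call(rbind, vals))
  names(d) <- cols
  d
}

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

#' Allowed units per physical parameter in run configurations
#' @noRd
.unit_whitelist <- list(
  q = "", r_MH = "angstrom", A_H = "rad/s", A_O = "rad/s",
  dH_M = "J/mol", dS_M = "J/mol/K", dH_MH = "J/mol", dS_MH = "J/mol/K",
  tau_S = "s", tau_R_298 = "s", E_R = "J/mol",
  a = "angstrom", D_298 = "m^2/s", E_D = "J/mol", B0_O17 = "T"
)

#' Read a run configuration
#'
#' Structured key-value (YAML) run configuration with explicit units on
#' every physical quantity. Top level keys: `command`, `seed`,
#' `output_dir`, `verbosity`, `datasets` (named paths), `OH_conc`,
#' `model`, and `parameters` (a map name -> \{value, unit, fixed,
#' lower, upper\}). Unknown keys anywhere are rejected, naming the
#' offending key and the nearest valid key; units are validated against
#' a per-parameter whitelist. No unit-less physical numbers are accepted.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with a ready-made
#'   `params` ([relax_params()]) element.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  top_allowed <- c("command", "seed", "output_dir", "verbosity",
                   "datasets", "parameters", "model", "OH_conc")
  .reject_unknown(names(cfg), top_allowed, "configuration key")
  pars <- cfg$parameters
  if (!is.null(pars)) {
    .reject_unknown(names(pars), .relax_par_names, "parameter")
    for (nm in names(pars)) {
      p <- pars[[nm]]
      .reject_unknown(names(p), c("value", "unit", "fixed", "lower",
                                  "upper", "citation"),
                      paste0("field of parameter '", nm, "'"))
      if (is.null(p$value))
        stop("parameter '", nm, "' lacks a value", call. = FALSE)
      want <- .unit_whitelist[[nm]]
      if (nzchar(want)) {
        if (is.null(p$unit))
          stop("parameter '", nm, "' lacks a unit (expected '", want, "')",
               call. = FALSE)
        if (!identical(p$unit, want))
          stop("parameter '", nm, "' has unit '", p$unit,
               "' but only '", want, "' is accepted", call. = FALSE)
      }
    }
    vals <- vapply(pars, function(p) as.numeric(p$value), numeric(1))
    fixed <- vapply(pars, function(p) isTRUE(p$fixed), logical(1))
    free <- names(pars)[!fixed]
    lower <- unlist(lapply(pars, function(p) p$lower))
    upper <- unlist(lapply(pars, function(p) p$upper))
    params <- relax_params(vals, free = free,
                           lower = lower, upper = upper,
                           model = if (is.null(cfg$model)) "water"
                           else cfg$model,
                           OH_conc = if (is.null(cfg$OH_conc)) 0
                           else cfg$OH_conc)
  } else params <- NULL
  structure(list(command = cfg$command, seed = cfg$seed,
                 output_dir = cfg$output_dir, verbosity = cfg$verbosity,
                 datasets = cfg$datasets, params = params),
            class = "run_config")
}

#' @noRd
.reject_unknown <- function(found, allowed, what) {
  unknown <- setdiff(found, allowed)
  if (length(unknown)) {
    key <- unknown[1]
    near <- allowed[which.min(utils::adist(key, allowed))]
    stop("unknown ", what, " '", key, "' (did you mean '", near, "'?)",
         call. = FALSE)
  }
  invisible(TRUE)
}
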