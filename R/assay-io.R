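#' Parameter containers for synthetic assays
#'
#' `saturation_params()` holds the molecular parameters of a saturation
#' assay; `competition_params()` those of a saturated competition assay;
#' `signal_model()` the linear signal constants of the CPM readout
#' (\eqn{CPM = B_{max} f_L + ns\,[L] + b_0}); `noise_model()` the seeded
#' measurement noise; `experiment_design()` the concentration grid.
#'
#' @param kd Single-site dissociation constant (molar), > 0.
#' @param alpha_l Nearest-neighbor Boltzmann factor, >= 0.
#' @return An object of the corresponding class.
#' @export
saturation_params <- function(kd, alpha_l = 1) {
  .check_pos(kd, "kd")
  .check_nonneg(alpha_l, "alpha_l", scalar = TRUE)
  structure(list(kd = kd, alpha_l = alpha_l), class = "saturation_params")
}

#' @param ec50_l Radioligand standalone midpoint \eqn{K_D/\alpha_L}
#'   (molar), > 0.
#' @param ec50_i Inhibitor standalone midpoint \eqn{K_I/\alpha_I} (molar),
#'   > 0.
#' @param beta Relative cross-cooperativity, >= 0.
#' @rdname saturation_params
#' @export
competition_params <- function(ec50_l, ec50_i, beta = 1) {
  .check_pos(ec50_l, "ec50_l")
  .check_pos(ec50_i, "ec50_i")
  .check_nonneg(beta, "beta", scalar = TRUE)
  structure(list(ec50_l = ec50_l, ec50_i = ec50_i, beta = beta),
            class = "competition_params")
}

#' @param bmax Maximum specific signal (CPM), > 0.
#' @param ns_slope Linear non-specific term (CPM per molar), >= 0.
#' @param baseline Constant background (CPM).
#' @rdname saturation_params
#' @export
signal_model <- function(bmax, ns_slope = 0, baseline = 0) {
  .check_pos(bmax, "bmax")
  .check_nonneg(ns_slope, "ns_slope", scalar = TRUE)
  stopifnot(is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  structure(list(bmax = bmax, ns_slope = ns_slope, baseline = baseline),
            class = "signal_model")
}

#' @param kind `"gaussian_absolute"` (sd = `scale` CPM) or
#'   `"gaussian_proportional"` (sd = `scale` times the clean signal
#'   magnitude).
#' @param scale Noise scale, >= 0; 0 gives noiseless data.
#' @param seed Integer seed; generation is deterministic given it.
#' @rdname saturation_params
#' @export
noise_model <- function(kind = c("gaussian_absolute", "gaussian_proportional"),
                        scale = 0, seed = 1L) {
  kind <- match.arg(kind)
  .check_nonneg(scale, "scale", scalar = TRUE)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(kind = kind, scale = scale, seed = as.integer(seed)),
            class = "noise_model")
}

#' @param conc_min,conc_max Concentration range (molar), 0 < min < max.
#' @param n_points Number of concentrations, >= 2.
#' @param spacing `"log"` (recommended for fitting) or `"linear"` (the
#'   scale on which most published fibril-binding data are reported, and
#'   which carries less information about the midpoint).
#' @rdname saturation_params
#' @export
experiment_design <- function(conc_min, conc_max, n_points = 12L,
                              spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  .check_pos(conc_min, "conc_min")
  .check_pos(conc_max, "conc_max")
  if (conc_min >= conc_max) stop("`conc_min` must be < `conc_max`")
  if (n_points < 2) stop("`n_points` must be >= 2")
  structure(list(conc_min = conc_min, conc_max = conc_max,
                 n_points = as.integer(n_points), spacing = spacing),
            class = "experiment_design")
}

.design_grid <- function(design) {
  with(design, switch(spacing,
    log = exp(seq(log(conc_min), log(conc_max), length.out = n_points)),
    linear = seq(conc_min, conc_max, length.out = n_points)))
}

.apply_noise <- function(clean, noise) {
  if (noise$scale == 0) return(clean)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(noise$seed)
  sd <- switch(noise$kind,
               gaussian_absolute = rep(noise$scale, length(clean)),
               gaussian_proportional = noise$scale * abs(clean))
  # negative CPM values are kept: clipping would bias low-signal fits
  clean + stats::rnorm(length(clean), 0, sd)
}

#' Generate a synthetic saturation dataset
#'
#' Evaluates the CPM signal model
#' \eqn{CPM = B_{max} f_L([L]/K_D, \alpha_L) + ns\,[L] + b_0} on the
#' design grid and adds seeded Gaussian noise.  Deterministic given the
#' noise seed; exactly noiseless at `scale = 0`.
#'
#' @param params A [saturation_params()].
#' @param signal A [signal_model()].
#' @param design An [experiment_design()].
#' @param noise A [noise_model()].
#' @return A saturation [binding_curve()].
#' @export
generate_saturation_dataset <- function(params, signal, design,
                                        noise = noise_model()) {
  stopifnot(inherits(params, "saturation_params"),
            inherits(signal, "signal_model"),
            inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  conc <- .design_grid(design)
  clean <- signal$bmax * saturation_fraction(conc / params$kd, params$alpha_l) +
    signal$ns_slope * conc + signal$baseline
  binding_curve(conc, .apply_noise(clean, noise), assay_type = "saturation",
                label = sprintf("synthetic saturation kd=%g alpha=%g",
                                params$kd, params$alpha_l))
}

#' Generate a synthetic competition dataset
#'
#' Places the midpoint at \eqn{IC_{50} = EC_{50,I} [L]/EC_{50,L}} and
#' evaluates \eqn{CPM = B_{max} f_L([I]/IC_{50}, \beta) + b_0} on the
#' design grid, plus seeded noise.
#'
#' @param params A [competition_params()].
#' @param radioligand_conc Free radioligand concentration (molar), > 0.
#' @inheritParams generate_saturation_dataset
#' @return A competition [binding_curve()].
#' @export
generate_competition_dataset <- function(params, radioligand_conc, signal,
                                         design, noise = noise_model()) {
  stopifnot(inherits(params, "competition_params"),
            inherits(signal, "signal_model"),
            inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  .check_pos(radioligand_conc, "radioligand_conc")
  ic50 <- ic50_saturated(params$ec50_i, radioligand_conc, params$ec50_l)
  conc <- .design_grid(design)
  clean <- signal$bmax * competition_fraction(conc / ic50, params$beta) +
    signal$baseline
  binding_curve(conc, .apply_noise(clean, noise), assay_type = "competition",
                radioligand_conc = radioligand_conc,
                label = sprintf("synthetic competition ic50=%g beta=%g",
                                ic50, params$beta))
}

#' Read and write binding curves as delimited text
#'
#' Curves are stored with a one-line header naming the concentration
#' column (`ligand_conc_M` for saturation, `inhibitor_conc_M` for
#' competition) and `cpm`.  Comma- and tab-delimited files are both
#' accepted; the delimiter is sniffed from the header.  Competition files
#' carry the radioligand concentration in a `# radioligand_conc_M:` comment
#' line, which `read_curve()` parses (an explicit `radioligand_conc`
#' argument overrides it).  Concentrations are serialized in scientific
#' notation and values round-trip to at least 12 significant digits.
#' Malformed rows are rejected with their line number.
#'
#' @param path File path.
#' @param radioligand_conc Optional override for competition files.
#' @return `read_curve()`: a [binding_curve()]. `write_curve()`: the path,
#'   invisibly.
#' @export
read_curve <- function(path, radioligand_conc = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  meta <- grep("^#", lines)
  rl_from_file <- NULL
  for (i in meta) {
    m <- regmatches(lines[i],
                    regexec("^#\\s*radioligand_conc_M:\\s*(\\S+)", lines[i]))[[1]]
    if (length(m) == 2L) rl_from_file <- as.numeric(m[2])
  }
  body_idx <- setdiff(seq_along(lines), meta)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  header_line <- lines[body_idx[1L]]
  delim <- if (grepl("\t", header_line)) "\t" else ","
  header <- trimws(strsplit(header_line, delim, fixed = TRUE)[[1]])
  conc_col <- intersect(c("ligand_conc_M", "inhibitor_conc_M"), header)
  if (length(conc_col) != 1L || !"cpm" %in% header) {
    stop("header must contain `cpm` and one of `ligand_conc_M`/`inhibitor_conc_M`; found: ",
         paste(header, collapse = ", "))
  }
  assay_type <- if (conc_col == "ligand_conc_M") "saturation" else "competition"
  ci <- match(conc_col, header)
  si <- match("cpm", header)
  rows_idx <- body_idx[-1L]
  conc <- numeric(length(rows_idx))
  cpm <- numeric(length(rows_idx))
  for (j in seq_along(rows_idx)) {
    ln <- rows_idx[j]
    cells <- trimws(strsplit(lines[ln], delim, fixed = TRUE)[[1]])
    if (length(cells) < max(ci, si)) {
      stop(sprintf("line %d: expected %d columns, found %d",
                   ln, length(header), length(cells)))
    }
    vals <- suppressWarnings(as.numeric(cells[c(ci, si)]))
    if (any(is.na(vals))) {
      stop(sprintf("line %d: non-numeric cell in '%s'", ln, lines[ln]))
    }
    if (vals[1] < 0) {
      stop(sprintf("line %d: negative concentration %g", ln, vals[1]))
    }
    conc[j] <- vals[1]
    cpm[j] <- vals[2]
  }
  if (is.null(radioligand_conc)) radioligand_conc <- rl_from_file
  binding_curve(conc, cpm, assay_type = assay_type,
                radioligand_conc = radioligand_conc)
}

#' @param curve A [binding_curve()].
#' @param delim `","` or `"\t"`.
#' @rdname read_curve
#' @export
write_curve <- function(curve, path, delim = ",") {
  stopifnot(inherits(curve, "binding_curve"), delim %in% c(",", "\t"))
  assay_type <- attr(curve, "assay_type")
  conc_col <- if (assay_type == "saturation") "ligand_conc_M" else "inhibitor_conc_M"
  lines <- character()
  if (assay_type == "competition") {
    lines <- sprintf("# radioligand_conc_M: %s",
                     formatC(attr(curve, "radioligand_conc"),
                             digits = 15, format = "e"))
  }
  lines <- c(lines, paste(conc_col, "cpm", sep = delim),
             paste(formatC(curve$concentration, digits = 15, format = "e"),
                   formatC(curve$signal, digits = 15, format = "g"),
                   sep = delim))
  writeLines(lines, path)
  invisible(path)
}
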