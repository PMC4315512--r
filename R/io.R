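# File interchange: traces and spike trains as plain CSV with a small
# key=value metadata header, configurations and reports as JSON.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a sample sequence to CSV
#'
#' Format: comment lines `# key=value` carrying `T` and `n_start`, then a
#' `time,value` table.  Floats are written with 17 significant digits so the
#' round trip is exact.
#'
#' @param samples a [sample_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(samples, path) {
  stopifnot(inherits(samples, "sample_seq"))
  df <- as.data.frame(samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# T=%s", fmt_num(samples$T)),
               sprintf("# n_start=%d", samples$n_start),
               "time,value"), con)
  writeLines(paste(fmt_num(df$time), fmt_num(df$value), sep = ","), con)
  invisible(path)
}

#' Read a sample sequence from CSV
#'
#' Accepts either `time,value` tables or value-only tables (the sampling
#' period then comes from a `# T=...` header line).  Timestamps are validated
#' to be uniform to within `1e-6 * T`.
#'
#' @param path input file path.
#' @return A [sample_sequence()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_idx]) {
    kv <- regmatches(l, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", l))[[1L]]
    if (length(kv) == 3L) meta[[kv[2L]]] <- kv[3L]
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  has_header <- grepl("[A-Za-z]", body[1L])
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        header = has_header)
  n_start <- as.integer(meta$n_start %||% 0L)
  if (ncol(df) >= 2L) {
    tt <- as.numeric(df[[1L]])
    vals <- as.numeric(df[[2L]])
    dt <- diff(tt)
    if (!length(dt)) stop("trace must contain at least two samples")
    T <- stats::median(dt)
    bad <- which(abs(dt - T) > 1e-6 * T)
    if (length(bad)) {
      stop(sprintf("non-uniform timestamps: row %d (time %g) breaks the sampling grid",
                   bad[1L] + 1L, tt[bad[1L] + 1L]))
    }
    n_start <- as.integer(round(tt[1L] / T))
    sample_sequence(vals, T = T, n_start = n_start)
  } else {
    if (is.null(meta$T)) stop("value-only trace needs a '# T=...' header line")
    sample_sequence(as.numeric(df[[1L]]), T = as.numeric(meta$T),
                    n_start = n_start)
  }
}

#' Write a spike train to CSV
#'
#' Two columns `time,amplitude` (amplitude blank when absent).
#'
#' @param spikes a [spike_train()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train"))
  amp <- spikes$amplitudes %||% rep(NA_real_, length(spikes$times))
  df <- data.frame(time = fmt_num(spikes$times),
                   amplitude = ifelse(is.na(amp), "", fmt_num(amp)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike train from CSV
#'
#' @param path input file path (columns `time[,amplitude]`).
#' @return A [spike_train()].
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path)
  amp <- if (ncol(df) >= 2L && any(!is.na(df[[2L]]))) as.numeric(df[[2L]]) else NULL
  spike_train(as.numeric(df[[1L]]), amp)
}

#' Write a location histogram to CSV
#'
#' @param hist a [build_histogram()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "location_histogram"))
  centers <- (hist$bin_edges[-1L] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  utils::write.csv(data.frame(bin_center = fmt_num(centers),
                              count = hist$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a coefficient table to CSV
#'
#' Columns `m`, `n`, `re`, `im`.
#'
#' @param coeffs an `fri_coeffs` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coeffs <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "fri_coeffs"))
  n0 <- attr(coeffs, "n0")
  m <- rep(0:(nrow(coeffs) - 1L), times = ncol(coeffs))
  n <- rep(n0 + 0:(ncol(coeffs) - 1L), each = nrow(coeffs))
  utils::write.csv(data.frame(m = m, n = n,
                              re = fmt_num(Re(coeffs)),
                              im = fmt_num(Im(coeffs))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The configuration drives the command-line interface; every field can be
#' overridden from a JSON file.  The JSON serialization round-trips.
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    T = 1 / 16,
    kernel = list(family = "espline", P = 7L),
    grid = list(N = 32L),
    signal = list(type = "dirac", K = 4L, amplitude = 1,
                  t_min = 0.5, t_max = 1.5, min_gap = 0.125,
                  alpha = 2, snr_db = Inf,
                  rate = 0.4, duration = 20, refractory = 0.5,
                  A = 1, tau_ca = 0.5),
    windows = list(big = list(N = 32L, P = 8L, K_max = 3L),
                   small = list(N = 8L, P = 3L)),
    thresholds = list(mu0 = 0.3, min_count_frac = 0.3, u_tol = 0.2,
                      bin_width_frac = 0.25)
  ), class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Fields present in the file override the defaults.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- modify_list_deep(cfg, user)
  }
  # JSON has no Inf literal; jsonlite writes it as the string "Inf"
  cfg$signal$snr_db <- as.numeric(cfg$signal$snr_db)
  structure(cfg, class = "run_config")
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      modify_list_deep(base[[nm]], new[[nm]])
    } else {
      new[[nm]]
    }
  }
  base
}

#' Write a run configuration to JSON
#'
#' @param cfg a `run_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# kernel from a config kernel spec: either explicit alphas or an order P
# resolved against the grid length N
config_kernel <- function(cfg) {
  ks <- cfg$kernel
  if (identical(ks$family, "gaussian")) return(make_gaussian(ks$sigma))
  if (!is.null(ks$alphas)) {
    a <- complex(real = ks$alphas[, 1L], imaginary = ks$alphas[, 2L])
    return(make_espline(a))
  }
  grid <- frequency_grid(ks$P, N = cfg$grid$N)
  make_espline(grid)
}
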