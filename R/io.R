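# Shared plain-text file formats: commented-header delimited tables for
# profiles and phase functions, JSON for parameter/report documents.

#' Write / read a reflectance profile
#'
#' Whitespace-delimited text with commented header lines. The first header
#' line declares the domain (`# domain=q` or `# domain=rho`); further
#' header lines record units, the delta weight and any scalar metadata
#' (seed, parameters), so a file is reproducible from its own header. The
#' column header line names the stored components.
#'
#' @param profile A [reflectance_profile()].
#' @param path File path.
#' @return `read_profile` returns a [reflectance_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "reflectance_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# domain=%s", attr(profile, "domain")), con)
  writeLines("# units=cm", con)
  writeLines(sprintf("# delta_weight=%.12g", attr(profile, "delta_weight")), con)
  meta <- attr(profile, "meta")
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.atomic(v) && length(v) == 1)
      writeLines(sprintf("# %s=%s", nm, format(v, digits = 12)), con)
  }
  keep <- vapply(profile, is.numeric, logical(1))
  writeLines(paste0("# columns: ", paste(names(profile)[keep], collapse = " ")), con)
  utils::write.table(format(as.data.frame(profile)[, keep, drop = FALSE], digits = 10),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    hit <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^#\\s*%s=", key), "", hit[1])
  }
  domain <- get("domain")
  if (is.null(domain) || !domain %in% c("q", "rho"))
    stop("missing or invalid '# domain=q|rho' header")
  colline <- grep("^#\\s*columns:", hdr, value = TRUE)
  if (!length(colline)) stop("missing '# columns:' header")
  cols <- strsplit(sub("^#\\s*columns:\\s*", "", colline[1]), "\\s+")[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  d <- utils::read.table(text = body, col.names = cols)
  if (any(diff(d[[1]]) <= 0)) stop("non-monotone abscissa in profile file")
  dw <- get("delta_weight")
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)=(.*)$", h))[[1]]
    if (length(m) == 3 && !m[2] %in% c("domain", "units", "delta_weight")) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(v)) m[3] else v
    }
  }
  reflectance_profile(domain, d[[1]], d[-1],
                      delta_weight = if (is.null(dw)) 0 else as.numeric(dw),
                      meta = meta,
                      allow_negative = TRUE)
}

#' Generate deterministic fixture files
#'
#' Writes small synthetic inputs used by tests and examples: a chord-
#' Gaussian SAA phase function, an exact Mie phase function, a noise-free
#' forward-model profile, or a profile with multiplicative log-normal
#' noise. All outputs are reproducible from the arguments and seed.
#'
#' @param kind One of `"gaussian-phase"`, `"mie-phase"`,
#'   `"forward-profile"`, `"noisy-profile"`.
#' @param path Output file path.
#' @param params Named list of parameters. `gaussian-phase`: `p_b`,
#'   `Theta`. `mie-phase`: `diameter`, `wavelength`, optional indices.
#'   `forward-profile`/`noisy-profile`: an [optical_properties()] in
#'   `props` plus optional `q` grid; `noisy-profile` also `noise_sd`
#'   (log-normal sigma, default 0.01).
#' @param seed Integer seed (used by `noisy-profile`).
#' @return The path, invisibly.
#' @export
generate_fixture <- function(kind, path, params = list(), seed = 1L) {
  kind <- match.arg(kind, c("gaussian-phase", "mie-phase", "forward-profile",
                            "noisy-profile"))
  if (kind == "gaussian-phase") {
    pf <- synthesize_saa(saa_params(params$p_b, params$Theta),
                         n_theta = params$n_theta %||% 1024)
    write_phase_function(pf, path)
  } else if (kind == "mie-phase") {
    susp <- sphere_suspension(params$diameter, params$wavelength,
                              n_sphere = params$n_sphere %||%
                                complex(real = refl_constants[["polystyrene"]]),
                              n_medium = params$n_medium %||% refl_constants[["water"]])
    write_phase_function(mie_phase_function(susp, params$n_theta %||% 1024), path)
  } else {
    props <- params$props
    stopifnot(inherits(props, "optical_properties"))
    mu_t <- props$mu_s + props$mu_a
    q <- params$q %||% c(0, 10^seq(log10(0.02 * mu_t), log10(60 * mu_t), length.out = 80))
    prof <- reflectance_total_q(q, props)
    if (kind == "noisy-profile") {
      set.seed(seed)
      sd <- params$noise_sd %||% 0.01
      fac <- exp(stats::rnorm(length(q), 0, sd))
      prof$total <- prof$total * fac
      attr(prof, "meta")$noise_sd <- sd
      attr(prof, "meta")$seed <- seed
    }
    write_profile(prof, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
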