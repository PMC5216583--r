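# ---------------------------------------------------------------------------
# Config-file interface: a YAML/JSON dialect specifying a design problem,
# the initial train, grouping and solver options. Angles in config files
# are degrees; power bounds are nominal rad^2.
# ---------------------------------------------------------------------------

#' Read a design configuration file
#'
#' Parses a YAML (or JSON) design configuration into the objects needed by
#' [solve_design()]. Supported top-level sections:
#'
#' * `problem`: `objective`, `N`, `tissue` (`T1`, `T2`, `tau`,
#'   `relaxation_off`), optional `K`, `target`, `weights`, `constraints`.
#'   Targets are either `{type: constant, value: , phase_deg: }`,
#'   `{type: inline, re: [], im: []}` or
#'   `{type: epg_of_train, alpha_deg: [], phi_deg: []}` (phases default to
#'   CPMG). Constraints use degree-valued bounds
#'   (`alpha_max_deg`) for peak amplitude.
#' * `fieldmaps`: optional path of a field-map container
#'   ([write_field_maps()]) switching the problem to pTx mode.
#' * `init`: `alpha_deg` and optional `phi_deg` (string `"cpmg"` allowed).
#' * `grouping`: either `{type: singletons}` or `{groups: [[0,..], ...]}`
#'   with 0-based pulse indices.
#' * `solver`: arguments of [solver_options()].
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return list with `problem`, `init`, `scheme`, `free`, `options`.
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  pc <- cfg$problem
  if (is.null(pc)) stop("config lacks a 'problem' section")
  N <- as.integer(pc$N)
  tc <- pc$tissue
  tissue <- tissue_params(T1 = tc$T1 %||% 1000, T2 = tc$T2 %||% 100,
                          tau = tc$tau %||% 10,
                          relaxation_off = isTRUE(tc$relaxation_off))
  target <- parse_target(pc$target, N, tissue, pc$K)
  weights <- parse_weights(pc$weights, N)
  constraints <- lapply(pc$constraints, function(cs) {
    if (!is.null(cs$alpha_max_deg)) {
      cs$alpha_max <- deg2rad(cs$alpha_max_deg)
      cs$alpha_max_deg <- NULL
    }
    cs
  })
  fields <- if (!is.null(cfg$fieldmaps)) read_field_maps(cfg$fieldmaps)
  problem <- design_problem(pc$objective, N = N, tissue = tissue,
                            K = pc$K, target = target, weights = weights,
                            constraints = constraints %||% list(),
                            fields = fields)
  init <- parse_init(cfg$init, N, fields)
  scheme <- parse_grouping(cfg$grouping, N)
  options <- do.call(solver_options, as.list(cfg$solver %||% list()))
  free <- parse_free(cfg$free, scheme, N)
  list(problem = problem, init = init, scheme = scheme, free = free,
       options = options)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_target <- function(tg, N, tissue, K) {
  if (is.null(tg)) return(NULL)
  type <- tg$type %||% "inline"
  switch(type,
    constant = rep(tg$value * exp(1i * deg2rad(tg$phase_deg %||% 90)), N - 1),
    inline = complex(real = unlist(tg$re),
                     imaginary = unlist(tg$im %||% rep(0, N - 1))),
    epg_of_train = epg_of_train(unlist(tg$alpha_deg),
                                if (is.null(tg$phi_deg)) NULL
                                else unlist(tg$phi_deg),
                                tissue, K),
    stop("unknown target type: ", type))
}

parse_weights <- function(w, N) {
  if (is.null(w)) return(NULL)
  if (is.list(w) && !is.null(w$default)) {
    out <- rep(w$default, N - 1)
    for (o in w$overrides) out[o$echo] <- o$weight
    return(out)
  }
  unlist(w)
}

parse_init <- function(ic, N, fields) {
  if (is.null(ic)) stop("config lacks an 'init' section")
  alpha <- unlist(ic$alpha_deg)
  phi <- if (is.null(ic$phi_deg) || identical(ic$phi_deg, "cpmg"))
    cpmg_phases(N) else unlist(ic$phi_deg)
  tr <- pulse_train(alpha, phi)
  if (is.null(fields)) tr else cp_mode_drive(tr, fields)
}

parse_grouping <- function(gc, N) {
  if (is.null(gc) || identical(gc$type, "singletons")) return(NULL)
  if (!is.null(gc$groups))
    return(build_grouping(lapply(gc$groups, function(g) unlist(g) + 1L), N))
  stop("unknown grouping specification")
}

parse_free <- function(fc, scheme, N) {
  if (is.null(fc)) return(NULL)
  G <- if (is.null(scheme)) N else scheme$G
  out <- list()
  for (nm in c("alpha", "phi", "drive")) {
    if (!is.null(fc[[nm]])) {
      v <- rep(TRUE, G)
      v[unlist(fc[[nm]]$fixed_groups) + 1L] <- FALSE
      out[[nm]] <- v
    }
  }
  out
}
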