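#' Write a source system to JSON
#'
#' Serializes the target marginal, source channels and source weights to a
#' JSON document with keys `p_y`, `y_outcomes`, `nu_s` and `sources` (a list
#' of `{name, outcomes, channel}` with the channel as a row-per-target-outcome
#' table). Probabilities are written as decimal numbers at full double
#' precision, so rational-valued fixtures round-trip bit-exactly.
#'
#' @param system An `rb_system`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_system_json <- function(system, path) {
  stopifnot(inherits(system, "rb_system"))
  doc <- list(
    p_y = system$p_y$probs,
    y_outcomes = system$p_y$outcomes,
    nu_s = system$nu_s$probs,
    sources = lapply(names(system$sources), function(nm) {
      ch <- system$sources[[nm]]
      list(name = nm, outcomes = ch$output_outcomes,
           channel = unname(lapply(seq_len(nrow(ch$probs)),
                                   function(i) ch$probs[i, ])))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a source system from JSON
#'
#' @param path Path to a document written by [write_system_json()] (the
#'   `y_outcomes` and `nu_s` keys are optional).
#' @return An `rb_system`.
#' @export
read_system_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$p_y) || is.null(doc$sources)) {
    stop("system file must contain `p_y` and `sources`", call. = FALSE)
  }
  y_out <- if (!is.null(doc$y_outcomes)) as.character(doc$y_outcomes) else
    as.character(seq_along(doc$p_y))
  p_y <- discrete_dist(as.numeric(doc$p_y), y_out)
  src_list <- doc$sources
  if (is.data.frame(src_list)) {
    src_list <- lapply(seq_len(nrow(src_list)), function(i) {
      list(name = src_list$name[i], outcomes = src_list$outcomes[[i]],
           channel = src_list$channel[[i]])
    })
  }
  sources <- list()
  for (src in src_list) {
    m <- src$channel
    if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
    m <- as.matrix(m)
    sources[[as.character(src$name)]] <-
      channel(m, y_out, as.character(src$outcomes))
  }
  nu <- if (!is.null(doc$nu_s)) as.numeric(doc$nu_s) else NULL
  source_system(p_y, sources, nu)
}

#' Write a bottleneck curve to CSV
#'
#' One row per tradeoff value with columns `beta`, `prediction_bits`,
#' `compression_bits`, `objective_bits`, `converged`, `n_iter`, then
#' `pred_src_<name>` and `comp_src_<name>` for every source. Numeric values
#' are printed at 12 significant digits.
#'
#' @param curve An `rb_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "rb_curve"))
  rows <- lapply(curve$points, function(p) {
    base <- list(beta = p$beta, prediction_bits = p$prediction,
                 compression_bits = p$compression, objective_bits = p$objective,
                 converged = p$converged, n_iter = p$n_iter)
    for (i in seq_len(nrow(p$per_source))) {
      base[[paste0("pred_src_", p$per_source$source[i])]] <- p$per_source$pred_s[i]
      base[[paste0("comp_src_", p$per_source$source[i])]] <- p$per_source$comp_s[i]
    }
    base
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a curve summary back from CSV
#'
#' @param path Path written by [write_curve_csv()].
#' @return A data frame (numeric columns restored).
#' @export
read_curve_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

log_line <- function(level, module, msg) {
  cat(sprintf("[%s] %s: %s\n", level, module, msg), file = stderr())
}

#' Command-line interface
#'
#' Subcommands: `gate` (emit a benchmark system as JSON), `info` (per-source
#' informations and the prediction/rate bounds), `blackwell` (exact
#' redundancy), `curve` (anneal over a tradeoff grid, CSV out), `at-rate`
#' (interpolated bottleneck value at a fixed compression rate). Run
#' `rb_cli("help")` for usage. Structured log lines go to standard error.
#'
#' @param argv Character vector of arguments (as from `commandArgs()`).
#' @return Integer exit code: 0 on success, 2 on validation errors, 1 on
#'   numerical failure.
#' @export
rb_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rb <command> [options]",
    "commands:",
    "  gate <unique|and|bsc|spin_overlap|copy> [--eps E[,E..]] --out PATH",
    "  info      --system PATH",
    "  blackwell --system PATH [--nq INT]",
    "  curve     --system PATH --out PATH [--beta-min F] [--beta-max F]",
    "            [--n-beta INT] [--objective linear|exp] [--nq INT]",
    "            [--restarts INT] [--seed INT] [--tol F] [--max-iter INT]",
    "  at-rate   --system PATH -R FLOAT [curve options]",
    sep = "\n")
  if (length(argv) == 0 || argv[1] %in% c("help", "--help", "-h")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  opts <- parse_flags(argv[-1])
  run <- function() {
    switch(cmd,
      gate = {
        if (length(opts$positional) < 1) stop("gate: missing gate name", call. = FALSE)
        eps <- if (!is.null(opts$eps)) as.numeric(strsplit(opts$eps, ",")[[1]]) else NULL
        sys <- make_gate(opts$positional[1], eps = eps)
        out <- opts$out %||% stop("gate: --out required", call. = FALSE)
        write_system_json(sys, out)
        log_line("INFO", "cli_io", sprintf("wrote %s system to %s", opts$positional[1], out))
      },
      info = {
        sys <- read_system_json(opts$system %||% stop("info: --system required", call. = FALSE))
        mi <- source_informations(sys)
        for (nm in names(mi)) cat(sprintf("I(%s;Y) = %.6f bits\n", nm, mi[nm]))
        cat(sprintf("prediction_bound = %.6f bits\n", prediction_bound(sys)))
        cat(sprintf("rate_bound = %.6f bits\n", rate_bound(sys)))
      },
      blackwell = {
        sys <- read_system_json(opts$system %||% stop("blackwell: --system required", call. = FALSE))
        nq <- if (!is.null(opts$nq)) as.integer(opts$nq) else NULL
        res <- blackwell_redundancy(sys, nq)
        log_line("INFO", "blackwell", sprintf("%d distinct vertices scored", res$n_vertices))
        cat(sprintf("blackwell_redundancy = %.6f bits\n", res$redundancy))
      },
      curve = ,
      `at-rate` = {
        sys <- read_system_json(opts$system %||% stop("--system required", call. = FALSE))
        grid <- default_beta_grid(as.numeric(opts$`beta-min` %||% 1e-2),
                                  as.numeric(opts$`beta-max` %||% 1e3),
                                  as.integer(opts$`n-beta` %||% 50L))
        obj <- switch(opts$objective %||% "exp",
                      exp = "exponential", linear = "linear",
                      stop("--objective must be linear or exp", call. = FALSE))
        cfg <- solver_config(objective = obj,
                             n_q = if (!is.null(opts$nq)) as.integer(opts$nq) else NULL,
                             max_iter = as.integer(opts$`max-iter` %||% 2000L),
                             tol = as.numeric(opts$tol %||% 1e-10),
                             n_restarts = as.integer(opts$restarts %||% 5L),
                             seed = as.integer(opts$seed %||% 0L))
        log_line("INFO", "rb_curve", sprintf("annealing %d beta values", length(grid)))
        crv <- anneal_curve(build_joint(sys), grid, cfg)
        if (cmd == "curve") {
          out <- opts$out %||% stop("curve: --out required", call. = FALSE)
          write_curve_csv(crv, out)
          log_line("INFO", "cli_io", sprintf("wrote curve to %s", out))
        } else {
          R <- as.numeric(opts$R %||% stop("at-rate: -R required", call. = FALSE))
          cat(sprintf("I_RB(%g) = %.6f bits\n", R, rb_at_rate(crv, R)))
        }
      },
      stop(sprintf("unknown command '%s'\n%s", cmd, usage), call. = FALSE))
    0L
  }
  code <- tryCatch(run(),
    validation_error = function(e) { log_line("ERROR", "cli_io", conditionMessage(e)); 2L },
    error = function(e) {
      msg <- conditionMessage(e)
      numerical <- grepl("underflow|converge|singular", msg, ignore.case = TRUE)
      log_line("ERROR", "cli_io", msg)
      if (numerical) 1L else 2L
    })
  invisible(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_flags <- function(args) {
  opts <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "-R") {
      opts$R <- args[i + 1L]; i <- i + 2L
    } else if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    } else {
      opts$positional <- c(opts$positional, a); i <- i + 1L
    }
  }
  opts
}
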