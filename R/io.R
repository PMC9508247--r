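#' Read an areal graph from an edge-list file
#'
#' Expects a two-column whitespace- or comma-delimited text file of
#' 0-based vertex ids, one undirected edge per line (lines starting with
#' \code{#} are ignored).
#'
#' @param path file path.
#' @param n optional vertex count (defaults to the largest id + 1).
#' @return An \code{\link{areal_graph}}.
#' @export
read_edge_list <- function(path, n = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[,[:space:]]+")
  if (any(lengths(parts) != 2L)) {
    stop("malformed edge list: every line must hold two vertex ids")
  }
  ij <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (anyNA(ij)) stop("malformed edge list: non-integer vertex id")
  areal_graph(ij + 1L, n = n)
}

#' Write an areal graph as an edge-list file
#'
#' @param graph an \code{\link{areal_graph}}.
#' @param path file path; ids are written 0-based.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "areal_graph"))
  utils::write.table(graph$edges - 1L, path, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read an areal graph from a dense adjacency matrix in CSV
#'
#' @param path CSV file holding a symmetric 0/1 matrix with zero diagonal.
#' @return An \code{\link{areal_graph}}.
#' @export
read_adjacency_csv <- function(path) {
  A <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(A) <- NULL
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (any(A != t(A))) stop("adjacency matrix must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency matrix must have zero diagonal")
  idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  areal_graph(idx, n = nrow(A))
}

#' Assemble a dataset for fitting from a data frame
#'
#' Pulls the response, covariate, offset, and coordinate columns named in
#' the configuration out of a data frame (typically read from CSV) and
#' returns them in the shapes the fitting functions expect.
#'
#' @param data data frame.
#' @param response name of the response column.
#' @param covariates character vector of covariate column names.
#' @param offset optional name of a column of expected counts; its log
#'   becomes the model offset (disease-mapping convention).
#' @param coords optional length-2 vector naming the x and y coordinate
#'   columns (point-level data).
#' @return List with \code{y}, \code{X}, \code{offset}, \code{coords}.
#' @export
assemble_data <- function(data, response, covariates, offset = NULL,
                          coords = NULL) {
  need <- c(response, covariates, offset, coords)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  }
  list(
    y = data[[response]],
    X = as.matrix(data[covariates]),
    offset = if (is.null(offset)) NULL else log(data[[offset]]),
    coords = if (is.null(coords)) NULL else as.matrix(data[coords])
  )
}

#' Run a complete fit from a configuration list
#'
#' Binds the modules into one call: read the data and spatial domain,
#' fit the two-stage model, bootstrap, and (optionally) write a JSON
#' report carrying the coefficients, intervals, copula estimates, both
#' AICs, the seed, and the fully resolved configuration.
#'
#' @param config named list with entries \code{data} (data frame or CSV
#'   path), \code{response}, \code{covariates}, optional \code{offset}
#'   column name, \code{family} (marginal), optional \code{size} /
#'   \code{theta}, \code{copula} (family tag), one of \code{edge_list}
#'   (path or edge matrix) or \code{coords} (coordinate column names),
#'   optional \code{taper_length}, \code{n_boot} (default 1000),
#'   \code{levels} (default 0.95), \code{seed} (default 1), and
#'   \code{residual_type}.
#' @param out optional path for the JSON fit report.
#' @return List with the \code{sgcrm_fit}, the \code{sgcrm_boot}, and the
#'   report list (invisibly written to \code{out} when given).
#' @export
run_fit_command <- function(config, out = NULL) {
  dat <- config$data
  if (is.character(dat)) dat <- utils::read.csv(dat)
  parts <- assemble_data(dat, config$response, config$covariates,
                         offset = config$offset, coords = config$coords)
  mspec <- marginal_spec(config$family,
                         size = config$size %||% 1L,
                         theta = config$theta,
                         offset = parts$offset)
  areal <- config$copula %in% c("car", "leroux")
  if (areal) {
    if (is.null(config$edge_list)) {
      stop("copula '", config$copula, "' needs an areal graph ('edge_list')")
    }
    domain <- if (is.character(config$edge_list)) {
      read_edge_list(config$edge_list, n = nrow(dat))
    } else {
      areal_graph(config$edge_list, n = nrow(dat))
    }
  } else {
    if (is.null(parts$coords)) {
      stop("copula '", config$copula, "' needs point coordinates ('coords')")
    }
    domain <- point_set(parts$coords)
  }
  cspec <- copula_spec(config$copula, domain,
                       taper_length = config$taper_length)
  seed <- config$seed %||% 1L
  residual_type <- config$residual_type %||% "deviance"
  fit <- fit_sgcrm(parts$X, parts$y, mspec, cspec,
                   residual_type = residual_type)
  boot <- sgcrm_bootstrap(fit, n_boot = config$n_boot %||% 1000L,
                          levels = config$levels %||% 0.95, seed = seed)
  report <- fit_report(fit, boot, config, seed)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(fit = fit, bootstrap = boot, report = report))
}

fit_report <- function(fit, boot, config, seed) {
  list(
    coefficients = as.list(fit$glm$coefficients),
    wald_intervals = interval_list(wald_intervals(fit, boot$levels[1L])),
    bootstrap_intervals = lapply(boot$intervals, interval_list),
    copula = list(family = fit$copula$family,
                  estimates = fit$copula$params,
                  loglik = fit$copula_loglik_max),
    theta = fit$glm$theta,
    aic_glm = fit$aic_glm,
    aic_cop = fit$aic_cop,
    residual_type = fit$residual_type,
    n_boot = boot$n_boot,
    dropped_refits = boot$dropped,
    seed = seed,
    config = config[setdiff(names(config), "data")]
  )
}

interval_list <- function(m) {
  stats::setNames(
    lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])),
    rownames(m) %||% paste0("beta", seq_len(nrow(m)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
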