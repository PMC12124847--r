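#' Read a protocol / tissue / sweep configuration file
#'
#' Configurations are YAML with up to three sections: \code{protocol}
#' (arguments of \code{\link{gre_protocol}}), \code{tissue} (arguments of
#' \code{\link{tissue_params}}) and \code{sweep} (arguments of
#' \code{\link{sweep_config}}). A preset with the reference acquisition protocol is
#' bundled; see \code{default_config_path()}.
#'
#' @param path YAML file path.
#' @return named list with any of \code{protocol} (a \code{tr_schedule}),
#'   \code{tissue} (a \code{tissue_params}), \code{sweep}
#'   (a \code{sweep_config}); unparsed sections are kept as lists under
#'   \code{raw}.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML sequences of mixed int/double arrive as lists; flatten to vectors
  simplify <- function(sec) lapply(sec, function(x) if (is.list(x)) unlist(x) else x)
  out <- list(raw = cfg)
  if (!is.null(cfg$protocol)) out$protocol <- do.call(gre_protocol, simplify(cfg$protocol))
  if (!is.null(cfg$tissue))   out$tissue   <- do.call(tissue_params, simplify(cfg$tissue))
  if (!is.null(cfg$sweep))    out$sweep    <- do.call(sweep_config, simplify(cfg$sweep))
  out
}

#' @rdname read_config
#' @export
default_config_path <- function() {
  system.file("extdata", "protocol_default.yaml", package = "epgspoil",
              mustWork = TRUE)
}
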