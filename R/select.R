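#' Select atoms from a molecular system
#'
#' Deterministic attribute-based selection; the result is ordered by position
#' in the atom table (file order, i.e. increasing serial for well-formed
#' files) and is independent of any frame's coordinates.
#'
#' @param system an `fc_system`.
#' @param chain chain id(s), or `NULL` for all.
#' @param resno residue numbers (any integer vector, e.g.
#'   `c(259:265, 301:306)`), or `NULL` for all.
#' @param name atom name(s), e.g. `"CA"`, or `NULL` for all.
#' @param component `"protein"`, `"glycan"`, `"other"`, or `NULL` for all.
#' @param heavy_only if `TRUE` (default) hydrogens are excluded, matching the
#'   heavy-atom conventions used by all descriptors.
#' @param allow_empty if `FALSE`, an empty result is an error; if `TRUE` an
#'   empty selection is returned with a warning.
#' @return integer atom indices of class `fc_selection` with a `provenance`
#'   attribute recording the query.
#' @export
select_atoms <- function(system, chain = NULL, resno = NULL, name = NULL,
                         component = NULL, heavy_only = TRUE,
                         allow_empty = FALSE) {
  stopifnot(inherits(system, "fc_system"))
  at <- system$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) {
    unknown <- setdiff(chain, system$chains)
    if (length(unknown) > 0)
      stop("unknown chain(s): ", paste(unknown, collapse = ", "),
           " (have: ", paste(system$chains, collapse = ", "), ")")
    keep <- keep & at$chain_id %in% chain
  }
  if (!is.null(resno)) keep <- keep & at$residue_number %in% resno
  if (!is.null(name)) keep <- keep & at$name %in% name
  if (!is.null(component))
    keep <- keep & atom_components(system) %in% component
  if (heavy_only) keep <- keep & at$is_heavy

  idx <- which(keep)
  prov <- sprintf(
    "chain=%s resno=%s name=%s component=%s heavy_only=%s",
    paste(chain %||% "*", collapse = ","),
    if (is.null(resno)) "*" else paste(range(resno), collapse = ".."),
    paste(name %||% "*", collapse = ","),
    paste(component %||% "*", collapse = ","), heavy_only
  )
  if (length(idx) == 0) {
    if (!allow_empty) stop("empty selection: ", prov)
    warning("empty selection: ", prov)
  }
  structure(idx, class = "fc_selection", provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fc_selection <- function(x, ...) {
  cat("fc_selection:", length(x), "atoms [",
      attr(x, "provenance"), "]\n")
  invisible(x)
}
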