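# Cell-type registry ---------------------------------------------------------
#
# The organ of Corti vocabulary: one row of inner hair cells (IHC), three rows
# of outer hair cells (OHC1-3, row 1 nearest the IHCs), and the interleaved
# supporting-cell types (inner phalangeal, Deiters', pillar, inner border
# cells). The registry is extensible so the pipeline generalizes to other
# curved epithelia; unknown labels are rejected at load time unless registered.

the <- new.env(parent = emptyenv())

.default_cell_types <- c("IHC", "OHC1", "OHC2", "OHC3", "IPhC", "DC", "PC", "IBC")

.registry <- function() {
  if (is.null(the$cell_types)) the$cell_types <- .default_cell_types
  the$cell_types
}

#' Registered cell-type labels
#'
#' The pipeline validates every annotation label against a registry seeded
#' with the eight organ-of-Corti cell types: inner hair cells (`IHC`), the
#' three outer hair cell rows (`OHC1`, `OHC2`, `OHC3`), inner phalangeal
#' cells (`IPhC`), Deiters' cells (`DC`), pillar cells (`PC`) and inner
#' border cells (`IBC`). Additional labels can be registered for other
#' tissues or annotation schemes.
#'
#' @param types Character vector of new labels to register.
#' @return `cell_types()` returns the character vector of registered labels.
#'   `register_cell_types()` returns the updated registry, invisibly.
#' @examples
#' cell_types()
#' register_cell_types("HensenC")
#' "HensenC" %in% cell_types()
#' reset_cell_types()
#' @export
cell_types <- function() .registry()

#' @rdname cell_types
#' @export
register_cell_types <- function(types) {
  stopifnot(is.character(types), !anyNA(types))
  the$cell_types <- union(.registry(), types)
  invisible(the$cell_types)
}

#' @rdname cell_types
#' @export
reset_cell_types <- function() {
  the$cell_types <- .default_cell_types
  invisible(the$cell_types)
}

.check_cell_types <- function(labels) {
  bad <- !labels %in% .registry()
  if (any(bad)) {
    offenders <- unique(labels[bad])
    rows <- which(bad)
    abort(c(
      sprintf(
        "Unregistered cell type%s: %s",
        if (length(offenders) > 1) "s" else "",
        paste0("\"", offenders, "\"", collapse = ", ")
      ),
      i = sprintf(
        "First offending row: %d. Use register_cell_types() to extend the registry.",
        rows[1]
      )
    ), class = "cochleogram_validation_error")
  }
  invisible(labels)
}
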