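#' Resource classes for the intrathecal administration procedure
#'
#' Three resource classes limit how many intrathecal (IT) administration
#' procedures an HD centre can deliver: the proceduralist performing the
#' lumbar puncture, the nursing staff assisting, and the chair/bed facility
#' occupied during the procedure. Nurses work in pairs during the CSF
#' collection and bolus injection steps, so the nurse class has a
#' concurrency of 2.
#'
#' @return Character vector of the three class names, in the fixed order
#'   used everywhere in the package (also the bottleneck tie-break order):
#'   `"proceduralist"`, `"nurse"`, `"facility"`.
#' @examples
#' resource_classes()
#' resource_concurrency("nurse")
#' @export
resource_classes <- function() {
  c("proceduralist", "nurse", "facility")
}

#' @rdname resource_classes
#' @param resource Resource class name.
#' @return `resource_concurrency()`: the number of simultaneous persons or
#'   slots of that class engaged in one procedure.
#' @export
resource_concurrency <- function(resource) {
  resource <- match_resource(resource)
  c(proceduralist = 1L, nurse = 2L, facility = 1L)[[resource]]
}

# Validate and normalise a resource-class name, with a clear error.
match_resource <- function(resource) {
  if (!is.character(resource) || length(resource) != 1L ||
      !resource %in% resource_classes()) {
    stop("unknown resource class: ", deparse(resource),
         " (expected one of ", paste(resource_classes(), collapse = ", "), ")",
         call. = FALSE)
  }
  resource
}
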