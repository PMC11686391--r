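# Region codes shared across modules. Stored as plain integers on the mesh;
# names are the public vocabulary.

#' Mesh region codes
#'
#' Named integer codes used in `mesh$region`: myocardium, blood_lv,
#' blood_ivc, bulk, catheter_body.
#' @export
REGION <- c(myocardium = 1L, blood_lv = 2L, blood_ivc = 3L, bulk = 4L,
            catheter_body = 5L)

#' Convert metres to millimetres and back
#' @param x numeric
#' @name units
#' @export
m_to_mm <- function(x) x * 1e3
#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
vm_to_vcm <- function(x) x / 100
#' @rdname units
#' @export
vcm_to_vm <- function(x) x * 100

# universal gas constant, J/(mol K)
.R_GAS <- 8.314
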