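#' Reference measurement design and generating parameters
#'
#' A two-attribute, eight-item, four-option design of the kind found in
#' short attitude surveys (e.g. math self-concept and math joy scales):
#' items 1-4 measure attribute 1, items 5-8 measure attribute 2, every
#' item has four ordered options (0..3).  `example_truth()` returns
#' calibrated point estimates for this design under each model, shipped as
#' the generating truth of the package's reference simulation study;
#' `example_prevalence()` the matching generating profile prevalence over
#' the profiles (0,0), (1,0), (0,1), (1,1).
#'
#' @param M options per item for `example_design()` (default 4).
#' @param model `"nrdm"`, `"ordm"` or `"mordm"`.
#' @return `example_qmatrix()`: a [q_matrix()]; `example_design()`: a
#'   [dcm_design()]; `example_truth()`: a natural-form [dcm_params()];
#'   `example_prevalence()`: a numeric prevalence vector.
#' @name reference_design
NULL

#' @rdname reference_design
#' @export
example_qmatrix <- function() {
  q_matrix(cbind(A1 = rep(c(1L, 0L), each = 4L),
                 A2 = rep(c(0L, 1L), each = 4L)),
           item_ids = paste0("Item", 1:8))
}

#' @rdname reference_design
#' @export
example_design <- function(M = 4L) dcm_design(example_qmatrix(), M = M)

#' @rdname reference_design
#' @export
example_prevalence <- function() c(0.351, 0.074, 0.156, 0.419)

#' @rdname reference_design
#' @export
example_truth <- function(model = c("ordm", "mordm", "nrdm")) {
  model <- match.arg(model)
  design <- example_design()
  terms <- c("a1", "a1", "a1", "a1", "a2", "a2", "a2", "a2")
  pseudo <- switch(model,
    ordm = {
      tab <- rbind(
        c(-0.390, -4.088, -5.321,  3.735),
        c(-0.834, -2.181, -3.127,  1.971),
        c(-1.533, -3.377, -3.194,  2.841),
        c( 0.289, -2.180, -3.784,  2.902),
        c( 1.991, -0.029, -1.352,  2.290),
        c( 1.352, -0.670, -2.586,  2.626),
        c( 0.071, -1.370, -2.297,  2.039),
        c( 0.646, -10.395, -12.733, 12.427))
      dcm_pseudo_params("ordm", design, lapply(1:8, function(i)
        list(intercepts = tab[i, 1:3],
             effects = stats::setNames(tab[i, 4L], terms[i]))))
    },
    mordm = {
      l0i <- c(5.834, 5.141, 4.491, 6.424, 10.313, 9.339, 7.948, 8.285)
      l1i <- c(2.472, 2.512, 2.732, 3.200, 3.262, 2.348, 1.622, 2.033)
      dcm_pseudo_params("mordm", design, lapply(1:8, function(i)
        list(intercept = l0i[i],
             effects = stats::setNames(l1i[i], terms[i]))),
        shared = list(list(intercepts = c(-6.204, -2.871, -3.781)),
                      list(intercepts = c(-7.893, -0.527, -2.111))))
    },
    nrdm = {
      tab <- rbind(
        c(-0.423, -10.710, -12.578,  3.619, 10.339, 10.981),
        c(-0.934,  -2.265,  -1.927,  2.149,  1.995,  0.744),
        c(-1.557,  -6.900, -10.818,  2.714,  6.354, 10.481),
        c( 0.269,  -4.540,  -3.491,  3.886,  5.319,  2.507),
        c( 1.986,  -0.036,  -1.241, 16.908,  2.756,  2.130),
        c( 1.347,  -0.716,  -2.305, 17.927,  2.780,  2.322),
        c( 0.296,  -1.850,  -2.255,  0.926,  2.857,  1.940),
        c( 0.642, -10.306, -11.038, 18.139, 12.357, 10.716))
      dcm_pseudo_params("nrdm", design, lapply(1:8, function(i)
        list(intercepts = tab[i, 1:3],
             effects = matrix(tab[i, 4:6], nrow = 1L,
                              dimnames = list(terms[i], NULL)))))
    })
  pseudo_to_natural(pseudo, design)
}
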