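#' Link functions for distribution parameters
#'
#' Minimal link-function objects used to map a distribution parameter onto the
#' unconstrained predictor scale. Only the links needed by the supported
#' families are provided: `"identity"` and `"log"`.
#'
#' @param name Link name, `"identity"` or `"log"`.
#' @return A list of class `fg_link` with elements `name`, `linkfun`
#'   (parameter -> predictor), `linkinv` (predictor -> parameter) and
#'   `dtheta_deta` (derivative of the parameter w.r.t. the predictor).
#' @examples
#' lk <- fg_link("log")
#' lk$linkinv(lk$linkfun(2.5))
#' @export
fg_link <- function(name) {
  switch(name,
    identity = structure(list(
      name = "identity",
      linkfun = function(theta) theta,
      linkinv = function(eta) eta,
      dtheta_deta = function(theta) rep_len(1, length(theta))
    ), class = "fg_link"),
    log = structure(list(
      name = "log",
      linkfun = function(theta) log(theta),
      linkinv = function(eta) exp(eta),
      dtheta_deta = function(theta) theta
    ), class = "fg_link"),
    stop("unknown link: ", name)
  )
}
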