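#' @keywords internal
#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance augment
#' @importFrom dplyr %>%
"_PACKAGE"

#' @export
dplyr::`%>%`

#' @export
generics::tidy

#' @export
generics::glance
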