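# Classed error conditions so callers and tests can discriminate failure
# modes without matching message strings.

abort_voxembed <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "voxembed_error"),
                      call = call))
}

#' @noRd
err_malformed_label <- function(msg) abort_voxembed(msg, "voxembed_malformed_label")
#' @noRd
err_invalid_map <- function(msg) abort_voxembed(msg, "voxembed_invalid_map")
#' @noRd
err_format <- function(msg) abort_voxembed(msg, "voxembed_format_error")
#' @noRd
err_unknown_label <- function(msg) abort_voxembed(msg, "voxembed_unknown_label")
#' @noRd
err_rank <- function(msg) abort_voxembed(msg, "voxembed_rank_error")
#' @noRd
err_undefined_distance <- function(msg) abort_voxembed(msg, "voxembed_undefined_distance")
#' @noRd
err_alignment <- function(msg) abort_voxembed(msg, "voxembed_alignment_error")
#' @noRd
err_domain <- function(msg) abort_voxembed(msg, "voxembed_domain_error")
#' @noRd
err_singular <- function(msg) abort_voxembed(msg, "voxembed_singular_design")
#' @noRd
err_no_data <- function(msg) abort_voxembed(msg, "voxembed_no_trainable_data")
#' @noRd
err_coverage <- function(msg) abort_voxembed(msg, "voxembed_coverage_error")
#' @noRd
err_spec <- function(msg) abort_voxembed(msg, "voxembed_spec_error")
#' @noRd
err_io <- function(msg) abort_voxembed(msg, "voxembed_io_error")
#' @noRd
err_contract <- function(msg) abort_voxembed(msg, "voxembed_contract_error")
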