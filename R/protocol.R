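#' Announce the host's trait for an interaction
#'
#' At the trait-matching stage the host names one of its traits for the
#' current interaction, chosen uniformly at random per interaction, so a
#' host with several traits presents different ones to different partners.
#'
#' @param host The host [agent()].
#' @return A trait identifier possessed by the host.
#' @export
select_host_trait <- function(host) {
  host$traits[[sample.int(length(host$traits), 1L)]]
}

#' Execute one visitor-host interaction
#'
#' Runs the staged negotiation between a visitor and a host. The stages are
#' executed strictly in order, and either party abandons the attempt at the
#' first ecological condition that fails:
#'
#' 1. *Habitat*: the host reveals its habitat. If the two differ, the
#'    interaction only proceeds when the visitor agrees to form a
#'    meta-community ([decide_metacommunity()]); otherwise the outcome is
#'    `quit_habitat`.
#' 2. *Trait*: the host announces a trait ([select_host_trait()]). If the
#'    visitor does not possess it, the outcome is `quit_trait`.
#' 3. *Complementarity*: trait sizes are exchanged and the visitor evaluates
#'    their complementarity ([complementarity_degree()]). If it does not
#'    exceed the configured threshold, the outcome is `quit_complementarity`.
#' 4. *Resources*: the visitor computes its demand and reward
#'    ([compute_demand()]), the host computes what it can offer
#'    ([host_has()]). If the offer is zero no resources change hands and the
#'    outcome is `quit_resources`; otherwise both agents settle the exchange
#'    and the outcome is `success`.
#'
#' Agent state is mutated only on `success`; every quit outcome leaves both
#' agents exactly as they were.
#'
#' @param visitor,host Active [agent()]s with the matching roles.
#' @param config A [sim_config()] supplying the negotiation parameters
#'   (complementarity threshold, demand/reward, costs, resource ceiling).
#' @param trace Optional connection or filename; when supplied, one plain-text
#'   line per stage is appended for debugging.
#' @return A list with components `record` (a one-row data frame with columns
#'   `visitor_id`, `host_id`, `outcome`, `is_metacommunity`, `trait`,
#'   `amount_offered`, `reward`), `visitor` and `host` (the possibly updated
#'   agents).
#' @export
run_interaction <- function(visitor, host, config = sim_config(),
                            trace = NULL) {
  if (visitor$role != "visitor" || host$role != "host") {
    stop("run_interaction needs a visitor and a host, in that order",
         call. = FALSE)
  }
  if (!is_active(visitor) || !is_active(host)) {
    stop("both participants must be active (resources >= min_resource)",
         call. = FALSE)
  }
  log_stage <- function(stage, detail) {
    if (!is.null(trace)) {
      cat(sprintf("%s -> %s : %s : %s\n", visitor$id, host$id, stage, detail),
          file = trace, append = TRUE)
    }
  }
  finish <- function(outcome, is_meta, trait = NA_character_,
                     offered = NA_real_, reward = NA_real_) {
    list(
      record = data.frame(
        visitor_id = visitor$id, host_id = host$id, outcome = outcome,
        is_metacommunity = is_meta, trait = trait,
        amount_offered = offered, reward = reward,
        stringsAsFactors = FALSE
      ),
      visitor = visitor, host = host
    )
  }

  # stage 1: habitat exchange / meta-community decision
  is_meta <- FALSE
  if (!same_habitat(visitor$habitat, host$habitat)) {
    is_meta <- decide_metacommunity(visitor, config$max_resource_init)
    if (!is_meta) {
      log_stage("habitat", "quit")
      return(finish("quit_habitat", FALSE))
    }
  }
  log_stage("habitat", if (is_meta) "metacommunity" else "shared")

  # stage 2: host announces a trait
  trait <- select_host_trait(host)
  if (!have_trait(visitor, trait)) {
    log_stage("trait", paste("quit:", trait))
    return(finish("quit_trait", is_meta, trait))
  }
  log_stage("trait", trait)

  # stage 3: trait sizes and complementarity
  degree <- complementarity_degree(visitor$trait_sizes[[trait]],
                                   host$trait_sizes[[trait]],
                                   config$max_trait_size)
  if (!is_complementary(degree, config$complementarity_threshold)) {
    log_stage("complementarity", sprintf("quit: %.3f", degree))
    return(finish("quit_complementarity", is_meta, trait))
  }
  log_stage("complementarity", sprintf("%.3f", degree))

  # stage 4: resource negotiation and settlement
  need <- compute_demand(visitor, degree, config$base_demand,
                         config$reward_fraction)
  offered <- host_has(host, need$amount, need$reward)
  if (offered <= 0) {
    log_stage("resources", "quit: nothing offered")
    return(finish("quit_resources", is_meta, trait))
  }
  visitor <- settle_visitor(visitor, offered, need$reward, is_meta,
                            config$living_cost,
                            config$metacommunity_surcharge)
  host <- settle_host(host, offered, need$reward)
  log_stage("resources", sprintf("offered=%.3f reward=%.3f", offered,
                                 need$reward))
  finish("success", is_meta, trait, offered, need$reward)
}
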