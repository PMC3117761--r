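#' Create an agent
#'
#' An agent is one species-individual in the simulated community. It takes
#' exactly one role for its whole lifetime: a `"host"` (the sessile partner,
#' e.g. a plant) or a `"visitor"` (the mobile partner, e.g. a pollinator).
#' Agents carry a habitat label, a set of traits with a size value for each
#' (the quantity on which complementarity between partners is judged, in the
#' spirit of bill length versus corolla depth), a pool of abstract resource
#' units, a survival floor below which they can no longer engage in
#' interactions, and a propensity to join meta-community (cross-habitat)
#' interactions.
#'
#' @param id Unique identifier, e.g. `"h1"` or `"v3"`.
#' @param role Either `"host"` or `"visitor"`. Fixed after construction.
#' @param habitat Small non-negative integer habitat label.
#' @param traits Non-empty character vector of trait identifiers.
#' @param trait_sizes Named numeric vector giving a size in
#'   `[0, max_trait_size]` for every element of `traits`.
#' @param resources Non-negative resource pool (abstract energy units).
#' @param min_resource Non-negative survival threshold: the agent must keep
#'   at least this much to stay active.
#' @param metacommunity_prob Probability in `[0, 1]` of agreeing to a
#'   cross-habitat interaction when otherwise eligible.
#' @param max_trait_size Upper bound used to validate `trait_sizes`.
#'
#' @return An object of class `mut_agent`.
#' @examples
#' a <- agent("v1", "visitor", habitat = 0, traits = c("t1", "t2"),
#'            trait_sizes = c(t1 = 2, t2 = 4.5), resources = 12)
#' a$role
#' @export
agent <- function(id, role, habitat, traits, trait_sizes, resources,
                  min_resource = 5, metacommunity_prob = 0.1,
                  max_trait_size = 5) {
  role <- match.arg(role, c("host", "visitor"))
  traits <- as.character(traits)
  if (length(traits) == 0) {
    stop("an agent must possess at least one trait", call. = FALSE)
  }
  if (anyDuplicated(traits)) {
    stop("duplicated trait identifiers", call. = FALSE)
  }
  if (!setequal(names(trait_sizes), traits)) {
    stop("trait_sizes must be named by exactly the possessed traits",
         call. = FALSE)
  }
  trait_sizes <- trait_sizes[traits]
  if (any(trait_sizes < 0) || any(trait_sizes > max_trait_size)) {
    stop("trait sizes must lie in [0, max_trait_size]", call. = FALSE)
  }
  if (resources < 0) stop("resources must be non-negative", call. = FALSE)
  if (min_resource < 0) stop("min_resource must be non-negative", call. = FALSE)
  if (metacommunity_prob < 0 || metacommunity_prob > 1) {
    stop("metacommunity_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(id = as.character(id), role = role, habitat = as.integer(habitat),
         traits = traits, trait_sizes = trait_sizes,
         resources = as.numeric(resources),
         min_resource = as.numeric(min_resource),
         metacommunity_prob = as.numeric(metacommunity_prob)),
    class = "mut_agent"
  )
}

#' @export
print.mut_agent <- function(x, ...) {
  cat(sprintf("<agent %s> role=%s habitat=%d resources=%.2f traits=%s\n",
              x$id, x$role, x$habitat, x$resources,
              paste(sprintf("%s(%.2f)", x$traits, x$trait_sizes),
                    collapse = " ")))
  invisible(x)
}

#' Is an agent able to interact?
#'
#' An agent is active while its resource pool is at or above its survival
#' floor; agents that fall below decline all further interactions (they are
#' not removed from the community).
#'
#' @param a A [agent()] object.
#' @return Logical scalar.
#' @export
is_active <- function(a) {
  a$resources >= a$min_resource
}

#' Select a host to visit
#'
#' A visitor initiating an interaction picks one partner uniformly at random
#' from the hosts currently available to it.
#'
#' @param visitor The visitor [agent()].
#' @param hosts Non-empty list of host agents.
#' @return One element of `hosts`.
#' @export
choose_host <- function(visitor, hosts) {
  if (length(hosts) == 0) {
    stop("no available host partners", call. = FALSE)
  }
  hosts[[sample.int(length(hosts), 1L)]]
}

#' Do two habitat labels match?
#'
#' @param habitat_visitor,habitat_host Integer habitat labels.
#' @return `TRUE` iff the labels are equal.
#' @export
same_habitat <- function(habitat_visitor, habitat_host) {
  habitat_visitor == habitat_host
}

#' Decide whether to join a meta-community interaction
#'
#' Cross-habitat (meta-community) interactions cost extra resources, so a
#' visitor only considers one when its own pool holds at least half the
#' community-wide resource maximum; an eligible visitor then agrees with its
#' individual meta-community propensity.
#'
#' @param visitor The visitor [agent()].
#' @param max_resource The community resource ceiling (initial maximum).
#' @return Logical: join the cross-habitat interaction?
#' @export
decide_metacommunity <- function(visitor, max_resource) {
  stopifnot(max_resource > 0)
  if (visitor$resources < max_resource / 2) {
    return(FALSE)
  }
  stats::runif(1) < visitor$metacommunity_prob
}

#' Does an agent possess a trait?
#'
#' @param visitor An [agent()].
#' @param trait Trait identifier.
#' @return `TRUE` iff `trait` is among the agent's traits.
#' @export
have_trait <- function(visitor, trait) {
  trait %in% visitor$traits
}

#' Complementarity between two trait sizes
#'
#' The degree to which two size values of a shared trait complement each
#' other: `1 - |size_visitor - size_host| / max_trait_size`. Equal sizes give
#' 1 (a perfect match), sizes at opposite ends of the scale give 0.
#'
#' @param size_visitor,size_host Size values in `[0, max_trait_size]`.
#' @param max_trait_size Positive size ceiling.
#' @return Degree of complementarity in `[0, 1]`.
#' @examples
#' complementarity_degree(2, 4, 5) # 0.6
#' @export
complementarity_degree <- function(size_visitor, size_host, max_trait_size) {
  if (max_trait_size <= 0) stop("max_trait_size must be positive", call. = FALSE)
  if (size_visitor < 0 || size_visitor > max_trait_size ||
      size_host < 0 || size_host > max_trait_size) {
    stop("trait sizes must lie in [0, max_trait_size]", call. = FALSE)
  }
  1 - abs(size_visitor - size_host) / max_trait_size
}

#' Is a complementarity degree sufficient for interaction?
#'
#' Strict comparison: the degree must exceed the threshold. With the default
#' threshold of 0 any non-zero complementarity permits the interaction.
#'
#' @param degree Complementarity degree in `[0, 1]`.
#' @param threshold Cut-off in `[0, 1]`.
#' @return Logical.
#' @export
is_complementary <- function(degree, threshold = 0) {
  stopifnot(degree >= 0, degree <= 1, threshold >= 0, threshold <= 1)
  degree > threshold
}

#' Visitor-side demand and reward
#'
#' From the complementarity degree the visitor computes the resource amount
#' it demands from the host and the reward it offers in return, both linear
#' in the degree: better-matched partners exchange more. The reward is capped
#' so the visitor never commits resources that would push it below its own
#' survival floor.
#'
#' @param visitor The visitor [agent()].
#' @param degree Complementarity degree in `[0, 1]`.
#' @param base_demand Demand at perfect complementarity (resource units).
#' @param reward_fraction Reward as a fraction of the demanded amount.
#' @return List with components `amount` and `reward`, both `>= 0`.
#' @export
compute_demand <- function(visitor, degree, base_demand = 4,
                           reward_fraction = 0.5) {
  stopifnot(degree >= 0, degree <= 1, base_demand >= 0,
            reward_fraction >= 0)
  amount <- base_demand * degree
  reward <- reward_fraction * amount
  spare <- max(0, visitor$resources - visitor$min_resource)
  reward <- min(reward, spare)
  list(amount = amount, reward = reward)
}

#' Host-side offer
#'
#' The host grants as much of the demanded amount as it can afford without
#' its pool (counting the incoming reward) dropping below its survival floor.
#'
#' @param host The host [agent()].
#' @param amount Amount demanded by the visitor, `>= 0`.
#' @param reward Reward offered by the visitor, `>= 0`.
#' @return The offered amount, `>= 0`.
#' @export
host_has <- function(host, amount, reward) {
  stopifnot(amount >= 0, reward >= 0)
  min(amount, max(0, host$resources + reward - host$min_resource))
}

#' Apply a completed exchange to the visitor
#'
#' The visitor gains the offered amount, pays the reward and a fixed living
#' cost per interaction, and pays an extra surcharge when the interaction
#' crossed habitats (meta-community interactions are more expensive, which is
#' why they are rare). The pool is floored at zero.
#'
#' @param visitor The visitor [agent()].
#' @param offered Amount received from the host.
#' @param reward Reward paid to the host (must not exceed the visitor's pool).
#' @param is_metacommunity Did the interaction cross habitats?
#' @param living_cost Per-interaction living cost (resource units).
#' @param metacommunity_surcharge Extra cost of a cross-habitat interaction.
#' @return The updated visitor agent.
#' @export
settle_visitor <- function(visitor, offered, reward, is_metacommunity = FALSE,
                           living_cost = 0.1, metacommunity_surcharge = 1) {
  stopifnot(offered >= 0, reward >= 0, reward <= visitor$resources)
  delta <- offered - reward - living_cost -
    if (is_metacommunity) metacommunity_surcharge else 0
  visitor$resources <- max(0, visitor$resources + delta)
  visitor
}

#' Apply a completed exchange to the host
#'
#' The host gains the reward and loses the amount it offered; the pool is
#' floored at zero.
#'
#' @param host The host [agent()].
#' @param offered Amount given to the visitor (at most `resources + reward`).
#' @param reward Reward received from the visitor.
#' @return The updated host agent.
#' @export
settle_host <- function(host, offered, reward) {
  stopifnot(offered >= 0, reward >= 0, offered <= host$resources + reward)
  host$resources <- max(0, host$resources + reward - offered)
  host
}
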