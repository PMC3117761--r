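#' Simulation configuration
#'
#' Collects every parameter of a community simulation. The defaults define
#' the reference experiment analysed throughout: ten hosts and fifteen
#' visitors (mirroring the usual excess of animal over plant species in
#' pollination webs) spread evenly over two habitats, initial resources drawn
#' from a truncated normal on `[5, 20]`, trait sizes up to five, a 0.1
#' probability of agreeing to cross-habitat interactions, and termination
#' after 300 successful interactions. The trait-structure defaults (a
#' universe of 10 traits, specialist-heavy trait counts between 1 and 6,
#' mildly skewed trait popularity, complementarity threshold 0.4) and the
#' cost defaults were calibrated once so that replicate runs occupy the
#' connectance and nestedness ranges typical of real mutualistic webs; see
#' the package vignette for the rationale behind each value.
#'
#' @param n_hosts,n_visitors Number of host and visitor agents.
#' @param n_habitats Number of habitats; agents of each role are spread
#'   round-robin so per-habitat counts differ by at most one.
#' @param min_resource_init,max_resource_init Bounds of the truncated-normal
#'   initial resource draw (mean at the midpoint, sd a quarter of the range).
#' @param max_trait_size Ceiling of the trait-size scale.
#' @param n_traits_universe Number of distinct traits in the community.
#' @param traits_per_agent Integer pair: each agent possesses between
#'   `traits_per_agent[1]` and `traits_per_agent[2]` traits.
#' @param trait_count_decay Geometric weight on the trait-count draw: an
#'   agent possesses `n` traits with probability proportional to
#'   `trait_count_decay^(n - 1)` over the `traits_per_agent` range. Values
#'   below 1 make specialists (few traits) common and generalists rare, the
#'   usual composition of mutualistic communities; 1 gives a uniform draw.
#' @param trait_popularity_decay Geometric weight on which traits are drawn:
#'   trait `j` of the universe is picked with weight proportional to
#'   `trait_popularity_decay^(j - 1)`, so values below 1 make some traits
#'   community-wide common and others rare; 1 makes all traits equally
#'   likely.
#' @param metacommunity_prob Per-agent probability of joining a
#'   cross-habitat interaction when eligible.
#' @param target_successes Number of successful interactions at which a run
#'   terminates.
#' @param seed Integer seed; every random draw of a run flows from it.
#' @param min_resource Survival floor shared by all agents; defaults to
#'   `min_resource_init`.
#' @param base_demand,reward_fraction Demand/reward parameters, see
#'   [compute_demand()].
#' @param complementarity_threshold Strict cut-off for [is_complementary()].
#' @param living_cost,metacommunity_surcharge Costs applied in
#'   [settle_visitor()].
#' @param max_attempts_factor Safety cap: a run aborts after
#'   `max_attempts_factor * target_successes` attempts, which flags
#'   configurations where success is impossible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$n_hosts
#' @export
sim_config <- function(n_hosts = 10, n_visitors = 15, n_habitats = 2,
                       min_resource_init = 5, max_resource_init = 20,
                       max_trait_size = 5, n_traits_universe = 10,
                       traits_per_agent = c(1, 6),
                       trait_count_decay = 0.6, trait_popularity_decay = 0.85,
                       metacommunity_prob = 0.1, target_successes = 300,
                       seed = 1, min_resource = min_resource_init,
                       base_demand = 4, reward_fraction = 0.5,
                       complementarity_threshold = 0.4,
                       living_cost = 0.2, metacommunity_surcharge = 1,
                       max_attempts_factor = 1000) {
  cfg <- list(
    n_hosts = as.integer(n_hosts), n_visitors = as.integer(n_visitors),
    n_habitats = as.integer(n_habitats),
    min_resource_init = as.numeric(min_resource_init),
    max_resource_init = as.numeric(max_resource_init),
    max_trait_size = as.numeric(max_trait_size),
    n_traits_universe = as.integer(n_traits_universe),
    traits_per_agent = as.integer(traits_per_agent),
    trait_count_decay = as.numeric(trait_count_decay),
    trait_popularity_decay = as.numeric(trait_popularity_decay),
    metacommunity_prob = as.numeric(metacommunity_prob),
    target_successes = as.integer(target_successes),
    seed = as.integer(seed),
    min_resource = as.numeric(min_resource),
    base_demand = as.numeric(base_demand),
    reward_fraction = as.numeric(reward_fraction),
    complementarity_threshold = as.numeric(complementarity_threshold),
    living_cost = as.numeric(living_cost),
    metacommunity_surcharge = as.numeric(metacommunity_surcharge),
    max_attempts_factor = as.numeric(max_attempts_factor)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_hosts < 1 || n_visitors < 1 || n_habitats < 1 ||
        n_traits_universe < 1 || target_successes < 1) {
      stop("all counts must be >= 1", call. = FALSE)
    }
    if (min_resource_init >= max_resource_init) {
      stop("min_resource_init must be below max_resource_init", call. = FALSE)
    }
    if (max_trait_size <= 0) stop("max_trait_size must be > 0", call. = FALSE)
    if (length(traits_per_agent) != 2 || traits_per_agent[1] < 1 ||
        traits_per_agent[1] > traits_per_agent[2] ||
        traits_per_agent[2] > n_traits_universe) {
      stop("traits_per_agent must be an increasing pair within the trait universe",
           call. = FALSE)
    }
    if (metacommunity_prob < 0 || metacommunity_prob > 1 ||
        complementarity_threshold < 0 || complementarity_threshold > 1) {
      stop("probabilities and thresholds must lie in [0, 1]", call. = FALSE)
    }
    if (min_resource < 0 || base_demand < 0 || reward_fraction < 0 ||
        living_cost < 0 || metacommunity_surcharge < 0) {
      stop("resource parameters must be non-negative", call. = FALSE)
    }
    if (trait_count_decay <= 0 || trait_popularity_decay <= 0) {
      stop("trait decay weights must be positive", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(x[[nm]], collapse = "-")))
  }
  invisible(x)
}

# one truncated-normal draw on [lo, hi], mean midpoint, sd = range/4
rtrunc_norm <- function(lo, hi) {
  mu <- (lo + hi) / 2
  sigma <- (hi - lo) / 4
  repeat {
    x <- stats::rnorm(1, mu, sigma)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Initialise a community of agents
#'
#' Creates `n_hosts` host and `n_visitors` visitor agents. Habitats are
#' assigned round-robin within each role, so the per-habitat counts differ by
#' at most one. Initial resources are drawn from a normal distribution
#' centred on the midpoint of `[min_resource_init, max_resource_init]` with
#' sd a quarter of the range, truncated to those bounds. Each agent receives
#' a uniformly random subset of the trait universe (size drawn from
#' `traits_per_agent`) and a uniform size on `[0, max_trait_size]` for each
#' possessed trait.
#'
#' Draws come from R's global RNG; seed it (or use [run_simulation()], which
#' seeds from `config$seed`) for reproducible communities.
#'
#' @param config A [sim_config()].
#' @return List of [agent()]s, hosts first.
#' @export
init_community <- function(config) {
  validate_sim_config(config)
  universe <- paste0("t", seq_len(config$n_traits_universe))
  count_range <- seq(config$traits_per_agent[1], config$traits_per_agent[2])
  count_weights <- config$trait_count_decay^(count_range -
                                               config$traits_per_agent[1])
  pop_weights <- config$trait_popularity_decay^(seq_along(universe) - 1)
  make <- function(prefix, role, i) {
    n_tr <- count_range[sample.int(length(count_range), 1L,
                                   prob = count_weights)]
    traits <- universe[sample.int(length(universe), n_tr,
                                  prob = pop_weights)]
    sizes <- stats::runif(n_tr, 0, config$max_trait_size)
    names(sizes) <- traits
    agent(
      id = paste0(prefix, i), role = role,
      habitat = (i - 1L) %% config$n_habitats,
      traits = traits, trait_sizes = sizes,
      resources = rtrunc_norm(config$min_resource_init,
                              config$max_resource_init),
      min_resource = config$min_resource,
      metacommunity_prob = config$metacommunity_prob,
      max_trait_size = config$max_trait_size
    )
  }
  c(lapply(seq_len(config$n_hosts), function(i) make("h", "host", i)),
    lapply(seq_len(config$n_visitors), function(i) make("v", "visitor", i)))
}

#' Run one community simulation
#'
#' Seeds the RNG from `config$seed`, initialises the community and then
#' repeats random encounters: an active visitor is picked uniformly at
#' random, selects an active host ([choose_host()]) and the full interaction
#' protocol is executed ([run_interaction()]). Every attempt (successful or
#' quit) is logged. The run ends when `target_successes` successful
#' interactions have completed. Identical configurations (including the seed)
#' reproduce identical runs.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: a list with `config`, `agents`
#'   (final states), `records` (data frame of all attempts, in order, with a
#'   `sequence_index` column), `n_success` and `initial_resources` (named
#'   vector, for resource book-keeping).
#' @examples
#' res <- run_simulation(sim_config(target_successes = 20, seed = 7))
#' res$n_success
#' @export
run_simulation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  agents <- init_community(config)
  names(agents) <- vapply(agents, `[[`, "", "id")
  roles <- vapply(agents, `[[`, "", "role")
  host_ids <- names(agents)[roles == "host"]
  visitor_ids <- names(agents)[roles == "visitor"]
  initial_resources <- vapply(agents, `[[`, 0, "resources")

  cap <- config$max_attempts_factor * config$target_successes
  buf_n <- 1024L
  rec <- list(
    visitor_id = character(buf_n), host_id = character(buf_n),
    outcome = character(buf_n), is_metacommunity = logical(buf_n),
    trait = character(buf_n), amount_offered = numeric(buf_n),
    reward = numeric(buf_n)
  )
  n_rec <- 0L
  n_success <- 0L

  while (n_success < config$target_successes) {
    if (n_rec >= cap) {
      stop(sprintf(
        "attempt cap reached (%d attempts, %d successes): configuration not viable",
        n_rec, n_success), call. = FALSE)
    }
    act_v <- visitor_ids[vapply(agents[visitor_ids], is_active, TRUE)]
    act_h <- host_ids[vapply(agents[host_ids], is_active, TRUE)]
    if (length(act_v) == 0 || length(act_h) == 0) {
      stop("no active agents left in one of the roles: configuration not viable",
           call. = FALSE)
    }
    visitor <- agents[[act_v[sample.int(length(act_v), 1L)]]]
    host <- choose_host(visitor, agents[act_h])
    out <- run_interaction(visitor, host, config)

    n_rec <- n_rec + 1L
    if (n_rec > buf_n) {
      buf_n <- buf_n * 2L
      rec <- lapply(rec, function(x) {
        length(x) <- buf_n
        x
      })
    }
    r <- out$record
    rec$visitor_id[n_rec] <- r$visitor_id
    rec$host_id[n_rec] <- r$host_id
    rec$outcome[n_rec] <- r$outcome
    rec$is_metacommunity[n_rec] <- r$is_metacommunity
    rec$trait[n_rec] <- r$trait
    rec$amount_offered[n_rec] <- r$amount_offered
    rec$reward[n_rec] <- r$reward

    if (r$outcome == "success") {
      agents[[out$visitor$id]] <- out$visitor
      agents[[out$host$id]] <- out$host
      n_success <- n_success + 1L
    }
  }

  records <- data.frame(lapply(rec, function(x) x[seq_len(n_rec)]),
                        stringsAsFactors = FALSE)
  records$sequence_index <- seq_len(n_rec)
  structure(
    list(config = config, agents = agents, records = records,
         n_success = n_success, initial_resources = initial_resources),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d successes in %d attempts (%d hosts, %d visitors, seed %d)\n",
    x$n_success, nrow(x$records), x$config$n_hosts, x$config$n_visitors,
    x$config$seed))
  invisible(x)
}

#' Run independent replicate simulations
#'
#' Repeats [run_simulation()] with seeds `base_seed, base_seed + 1, ...`,
#' keeping every other configuration field fixed, so replicates differ only
#' in the agents' random initialisation and encounter history.
#'
#' @param config A [sim_config()]; its `seed` field is overridden per run.
#' @param n_runs Number of replicates, `>= 1`.
#' @param base_seed Seed of the first replicate.
#' @return List of `sim_result` objects.
#' @export
run_replicates <- function(config, n_runs, base_seed = config$seed) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1L)
    run_simulation(cfg)
  })
}

#' Sensitivity sweep over one configuration parameter
#'
#' For each candidate value of a configuration field, runs `n_runs`
#' replicates and records the connectance and NODF nestedness of each
#' resulting network, supporting sensitivity analyses of the community
#' structure with respect to the model parameters.
#'
#' @param config Baseline [sim_config()].
#' @param parameter Name of a `sim_config` field.
#' @param values Vector (or list, for vector-valued fields) of values to try.
#' @param n_runs Replicates per value.
#' @param base_seed Seed of the first replicate of each value.
#' @return Data frame with columns `parameter`, `value`, `replicate`, `seed`,
#'   `connectance`, `nodf` (NODF is `NA` when the network matrix is too
#'   degenerate for the metric).
#' @export
sweep_parameter <- function(config, parameter, values, n_runs = 3,
                            base_seed = config$seed) {
  if (!parameter %in% names(config)) {
    stop(sprintf("unknown configuration parameter '%s'", parameter),
         call. = FALSE)
  }
  if (!is.list(values)) values <- as.list(values)
  rows <- lapply(seq_along(values), function(vi) {
    cfg <- config
    cfg[[parameter]] <- values[[vi]]
    cfg <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
    runs <- run_replicates(cfg, n_runs, base_seed)
    do.call(rbind, lapply(seq_along(runs), function(ri) {
      net <- build_network(runs[[ri]]$records)
      nodf_val <- tryCatch(nodf(to_matrix(net)), error = function(e) NA_real_)
      data.frame(
        parameter = parameter,
        value = paste(values[[vi]], collapse = "-"),
        replicate = ri, seed = base_seed + ri - 1,
        connectance = connectance(net), nodf = nodf_val,
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, rows)
}

#' Total resources held by a set of agents
#'
#' @param agents List of [agent()]s (e.g. `sim_result$agents`).
#' @return Numeric scalar.
#' @export
total_resources <- function(agents) {
  sum(vapply(agents, `[[`, 0, "resources"))
}

#' Read / write a simulation configuration file
#'
#' Configurations are stored as a flat key-value YAML document whose keys
#' are exactly the fields of [sim_config()].
#'
#' @param path File path.
#' @return `read_sim_config()` returns a validated [sim_config()];
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration keys: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] to serialise.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), unname), path)
  invisible(path)
}

#' Write the attempt log of a run as CSV
#'
#' One row per protocol attempt, successful or not, in simulation order:
#' columns `visitor_id`, `host_id`, `outcome`, `metacommunity`, `trait`,
#' `offered`, `reward`.
#'
#' @param result A `sim_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attempt_log <- function(result, path) {
  r <- result$records
  out <- data.frame(
    visitor_id = r$visitor_id, host_id = r$host_id, outcome = r$outcome,
    metacommunity = r$is_metacommunity, trait = r$trait,
    offered = r$amount_offered, reward = r$reward,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a simulation result to JSON
#'
#' Writes the configuration, the full attempt log and the final agent states
#' (id, role, habitat, traits, sizes, resources) as one JSON document.
#'
#' @param result A `sim_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_result_json <- function(result, path) {
  agents <- lapply(result$agents, function(a) {
    list(id = a$id, role = a$role, habitat = a$habitat, traits = a$traits,
         trait_sizes = as.list(a$trait_sizes), resources = a$resources,
         min_resource = a$min_resource,
         metacommunity_prob = a$metacommunity_prob)
  })
  doc <- list(
    config = lapply(unclass(result$config), unname),
    n_success = result$n_success,
    records = result$records,
    final_agents = unname(agents)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
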