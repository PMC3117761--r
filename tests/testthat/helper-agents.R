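# Builders for small, fully specified agents used across the test files.

make_visitor <- function(id = "v1", habitat = 0, traits = c("t1", "t2"),
                         sizes = c(t1 = 2, t2 = 4), resources = 15,
                         min_resource = 5, metacommunity_prob = 0) {
  agent(id, "visitor", habitat = habitat, traits = traits,
        trait_sizes = sizes[traits], resources = resources,
        min_resource = min_resource,
        metacommunity_prob = metacommunity_prob)
}

make_host <- function(id = "h1", habitat = 0, traits = c("t1", "t2"),
                      sizes = c(t1 = 2, t2 = 4), resources = 20,
                      min_resource = 5) {
  agent(id, "host", habitat = habitat, traits = traits,
        trait_sizes = sizes[traits], resources = resources,
        min_resource = min_resource)
}

# a config under which a co-habiting pair with a shared trait of equal sizes
# always succeeds with amount 4 and reward 2
ample_config <- function(...) {
  sim_config(complementarity_threshold = 0, living_cost = 0.1, ...)
}

# records data frame shorthand for network-construction tests
success_records <- function(hosts, visitors) {
  data.frame(visitor_id = visitors, host_id = hosts, outcome = "success",
             stringsAsFactors = FALSE)
}
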