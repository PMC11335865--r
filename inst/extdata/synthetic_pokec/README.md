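# Synthetic Pokec-dialect fixture

A 200-node directed network generated by `sociomix::generate_users()`,
`generate_following()`, and `generate_reciprocation()` with the default
`synth_config(n_nodes = 200, mean_out_degree = 5)` and written in the Pokec
snapshot dialect by `write_fixture()`. Entirely synthetic — no real users.
Used by the end-to-end examples and tests; regenerate with the same calls
if needed.
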