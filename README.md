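# fespike

Supervised learning of precisely timed spikes in leaky
integrate-and-fire (LIF) neurons, for computational neuroscientists
studying spike-timing-based coding and plasticity rules.

Temporal-coding models ask a single neuron to answer a spatiotemporal
input pattern — hundreds of afferent spike trains — with a *specific*
output spike train, accurate to milliseconds. `fespike` implements a
first-error learning rule for this task: in every trial the synaptic
weights are adjusted exactly once, at the earliest time the output goes
wrong.

## Model and rule

The neuron integrates weighted postsynaptic potentials and resets after
each output spike:

    V(t) = Σᵢ wᵢ Σⱼ K(t − tᵢʲ) − ϑ Σⱼ exp(−(t − tₛʲ)/τ_m),
    K(x) = V_norm (e^(−x/τ_m) − e^(−x/τ_s)),   max K = 1.

Each desired spike time carries a tolerance window of width ε grid
steps. The first wrong output spike time `t_err` is a stray spike
outside every window (type a), a duplicate inside a satisfied window
(type b), or a window that closes unfilled (type c). Type c triggers a
gradient *increment* of the weights toward firing at `t_err` — the
accumulated PSP of each afferent at `t_err`, plus chain-rule terms
(scaled by a rate `S_r`) that reinforce the potential at all earlier
desired times through the linearized threshold crossing. Types a and b
trigger a *decrement* proportional to the accumulated PSP at `t_err`
alone. Learning quality is scored by the correlation metric `C`: the
cosine similarity of the two spike trains after Gaussian filtering
(σ = 2 ms); `C = 1` means the target is reproduced exactly.

The package also provides homogeneous-Poisson and jitter/deletion/
insertion noise generators, a three-class spatiotemporal classification
harness with per-class template neurons, a dynamic target-determination
strategy with population readout for template-free decoding, named
experiment protocols (`run_experiment()`), and a small CLI
(`inst/cli/fespike`).

## Worked example

Train a 100-afferent neuron (10 Hz Poisson input, 300 ms) to reproduce
a 14-spike target train with ε = 3:

```r
library(fespike)
pat    <- poisson_pattern(100, rate = 10, duration = 300, seed = 1)
target <- poisson_train(60, 300, seed = 2, t_min = 1, min_gap = 3)
rec    <- fe_train(pat, target,
                   learn_config(epsilon = 3, max_epochs = 4000, seed = 3))
rec
#> first-error training: converged after 835 update(s); best C = 0.9623 at epoch 835

tr <- simulate_lif(pat, rec$weights)
rbind(output = head(tr$output_spikes, 8), target = head(target, 8))
#> output 30 52 72 82 112 120 133 164
#> target 31 51 73 83 111 121 133 163
correlation_c(tr$output_spikes, target, duration = 300)
#> [1] 0.962337
```

Every output spike sits within ±1 ms of its target — inside the ε = 3
tolerance window — so training has converged; `C ≈ 0.96` rather than 1
reflects exactly those sub-window offsets. With ε = 1 convergence
forces `C = 1`.

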