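# sporenet

Reward-driven synaptic sampling in closed-loop spiking networks.

`sporenet` is an R package for studying a biologically plausible
reinforcement-learning rule — *synaptic sampling with online
reinforcement learning* (SPORE) — inside a spiking network that controls
an agent in a simulated visuomotor environment. It is aimed at
computational neuroscientists who want to probe the rule's learning
dynamics, annealing behavior and synapse sparsification on a single CPU,
without a neural simulator, a robotics middleware stack, or hours of
wall-clock time.

## The model

Each plastic synapse carries the state $(y_i, e_i, g_i, \theta_i, w_i)$:
a filtered pre-synaptic trace, an eligibility trace, a reward-gradient
estimate, the sampled parameter, and the weight. The fast dynamics
(forward Euler, 1 ms)

$$\dot e_i = -e_i/\tau_e + w_i y_i (z_i^{post} - \rho_i^{post}), \qquad
\dot g_i = -g_i/\tau_g + r(t)\, e_i$$

feed the slow parameter SDE (Euler–Maruyama, 100 ms)

$$d\theta_i = \beta\big(c_p(\mu - \theta_i) + c_g g_i\big)\,dt
+ \sqrt{2 T \beta}\, dW_i, \qquad
w_i = \begin{cases} w_0 e^{\theta_i - \theta_0} & \theta_i > 0\\
0 & \text{otherwise,}\end{cases}$$

so the network does not converge to a point optimum but keeps sampling
parameter vectors from a posterior-like distribution (prior × expected
reward), with temperature $T$ setting exploration and the learning rate
optionally annealed as $\beta(t) = \beta_0 e^{-\lambda \Delta \lfloor
t/\Delta\rfloor}$ every $\Delta = 600$ s.

Around the rule, the package provides the full closed loop: procedural
scene rendering, an event-camera (DVS) simulation with address events,
spike encoders (per-pixel + row/column axis neurons for reaching; 8×8
windowed rate neurons for lane following), stochastic point-process
neurons, population-vector velocity decoding and ratio-based discrete
steering, the two environments with their published reward functions, and
analysis metrics (reach rate per 250 s, weak-weight counts below 0.07,
active-synapse percentages, per-pixel policy vector fields).

## A worked example

```r
library(sporenet)

setup <- reduced_reaching_setup()      # desk-scale reaching task
run <- run_experiment("reaching", duration = 300, seed = 1,
                      spore = setup$spore, net = setup$net,
                      env = setup$env, record_dt = 0.1)
summary(run)
```

```
reaching run, 300 s (seed 1)
  resets: 1; mean reward: 4.706
  weak weights (< 0.07): 96 -> 93 of 640 (85% active)
  resets per window:
 window_start count
            0     1
          250     0
```

The summary reports: how often the ball reached the target (one reset in
the first 250 s window — after five simulated minutes this policy is still
essentially random), the mean of the continuous reward stream, and
sparsification: of the 640 plastic synapses, 96 started retracted
(weight 0, i.e. below the 0.07 weak-weight threshold) and 93 are weak
after 300 s, so 85% of synapses are active. Longer runs with learning
enabled drive the weak count up substantially while reach performance
improves; `plot(run)` shows the reward trace and the final weight
histogram, and `policy_map(run)` gives the per-pixel motion vectors with
their angular correctness toward the target.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/sporenet-cli.R", package = "sporenet"))')" \
    run reaching --duration 10 --seed 1 --out my-run
```

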