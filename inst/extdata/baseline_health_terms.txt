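diet
dieting
health
healthy
nutrition
wellness
fitness
calories
weight
exercise
eating
vegan
keto
workout
gym
wellbeing
mindfulness
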