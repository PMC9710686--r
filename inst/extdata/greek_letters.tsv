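name	lower	upper	initial
alpha	α	Α	a
beta	β	Β	b
gamma	γ	Γ	g
delta	δ	Δ	d
epsilon	ε	Ε	e
zeta	ζ	Ζ	z
eta	η	Η	e
theta	θ	Θ	t
iota	ι	Ι	i
kappa	κ	Κ	k
lambda	λ	Λ	l
mu	μ	Μ	m
nu	ν	Ν	n
xi	ξ	Ξ	x
omicron	ο	Ο	o
pi	π	Π	p
rho	ρ	Ρ	r
sigma	σ	Σ	s
tau	τ	Τ	t
upsilon	υ	Υ	u
phi	φ	Φ	f
chi	χ	Χ	c
psi	ψ	Ψ	p
omega	ω	Ω	o
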