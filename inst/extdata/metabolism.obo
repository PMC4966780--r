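format-version: 1.2

[Term]
id: GO:0006139
name: nucleobase-containing compound metabolic process
namespace: biological_process
is_a: GO:0044237
is_a: GO:0044238

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0008152
name: metabolic process
namespace: biological_process
is_a: GO:0008150

[Term]
id: GO:0009987
name: cellular process
namespace: biological_process
is_a: GO:0008150

[Term]
id: GO:0034641
name: cellular nitrogen compound metabolic process
namespace: biological_process
is_a: GO:0044237

[Term]
id: GO:0043170
name: macromolecule metabolic process
namespace: biological_process
is_a: GO:0071704

[Term]
id: GO:0044237
name: cellular metabolic process
namespace: biological_process
is_a: GO:0008152
is_a: GO:0009987

[Term]
id: GO:0044238
name: primary metabolic process
namespace: biological_process
is_a: GO:0071704

[Term]
id: GO:0044260
name: cellular macromolecule metabolic process
namespace: biological_process
is_a: GO:0034641
is_a: GO:0043170
is_a: GO:0044262

[Term]
id: GO:0044262
name: cellular carbohydrate metabolic process
namespace: biological_process
is_a: GO:0044237

[Term]
id: GO:0071704
name: organic substance metabolic process
namespace: biological_process
is_a: GO:0008152

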