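format-version: 1.2

[Term]
id: TA:0000001
name: TA:0000001
namespace: category_a

[Term]
id: TA:0000002
name: TA:0000002
namespace: category_a
is_a: TA:0000001

[Term]
id: TA:0000003
name: TA:0000003
namespace: category_a
relationship: part_of TA:0000001

[Term]
id: TA:0000004
name: TA:0000004
namespace: category_a
is_a: TA:0000002

[Term]
id: TA:0000005
name: TA:0000005
namespace: category_a
is_obsolete: true

[Term]
id: TB:0000001
name: TB:0000001
namespace: category_b

[Term]
id: TB:0000002
name: TB:0000002
namespace: category_b
is_a: TB:0000001

[Term]
id: TB:0000003
name: TB:0000003
namespace: category_b
is_a: TB:0000001

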