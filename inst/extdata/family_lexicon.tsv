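surface	base_name
dad	Father
daddy	Father
papa	Father
mom	Mother
mommy	Mother
mama	Mother
momma	Mother
grandma	Grandmother
granny	Grandmother
nana	Grandmother
grandpa	Grandfather
granddad	Grandfather
grandad	Grandfather
sis	Sister
bro	Brother
kid	Child
children	Child
auntie	Aunt
aunty	Aunt
sib	Sibling
half-sister	Sister
half-brother	Brother
stepmother	Mother
stepfather	Father
stepsister	Sister
stepbrother	Brother
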