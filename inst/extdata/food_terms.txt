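milk
yogurt and cheese
cooking oil
butter
margarine and shortening
apples
oranges
bananas
berries and melons
wheat
rice
oats
barley
bread and pasta
chicken
fish
turkey
pork and beef
candy
soft drinks
cake
pie and ice cream
spinach
carrots
onions
peppers
broccoli
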