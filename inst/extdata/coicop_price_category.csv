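coicop,price_category
1.1.1.1.1,food_nonalcoholic
1.1.1.4.1,food_nonalcoholic
1.1.2.1.1,food_nonalcoholic
1.1.2.5.1,food_nonalcoholic
1.1.4.1.1,food_nonalcoholic
1.1.6.1.1,food_nonalcoholic
1.1.6.2.1,food_nonalcoholic
1.1.7.1.1,food_nonalcoholic
1.2.1.1.1,food_nonalcoholic
1.2.2.2.1,food_nonalcoholic
2.1.1.1.1,alcohol_tobacco
2.1.3.1.1,alcohol_tobacco
2.2.1.1.1,alcohol_tobacco
11.1.1.1.1,restaurants_hotels
11.1.1.2.1,restaurants_hotels
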