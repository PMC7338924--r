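taxonomy,category,keyword,ambiguous_flag,context_list
flavor,Fruit,strawberry,0,
flavor,Fruit,mango,0,
flavor,Fruit,watermelon,0,
flavor,Fruit,blueberry,0,
flavor,Fruit,green apple,0,
flavor,Menthol or Mint,menthol,0,
flavor,Menthol or Mint,mint,0,
flavor,Menthol or Mint,peppermint,0,
flavor,Menthol or Mint,spearmint,0,
flavor,Tobacco,tobacco,1,flavor;flavour;e-liquid;e-juice;ejuice;eliquid;juice;vape;blend;taste
flavor,Tobacco,ry4,0,
flavor,Tobacco,virginia tobacco,0,
flavor,Sweet,custard,0,
flavor,Sweet,caramel,0,
flavor,Sweet,vanilla,0,
flavor,Sweet,candy,0,
flavor,Sweet,butterscotch,0,
flavor,Beverage,coffee,0,
flavor,Beverage,cola,0,
flavor,Beverage,lemonade,0,
flavor,Beverage,mojito,0,
flavor,Mixed,fruit medley,0,
flavor,Mixed,tropical punch,0,
flavor,Mixed,berry mix,0,
flavor,Other,cinnamon,0,
flavor,Other,clove,0,
flavor,Other,bubblegum,0,
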